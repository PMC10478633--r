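#' Peak finder configuration
#'
#' @param window Edge of the local square window used for candidate
#'   thresholding and background modelling (pixels, default 32).
#' @param snr_threshold Minimum SNR for a candidate to become a peak
#'   (default 6); the comparison is `>=`, so a candidate at exactly the
#'   threshold is accepted.
#' @param max_peaks Cap on candidates per frame, applied after sorting by
#'   intensity descending (default 1024).
#' @param min_peaks_for_hit A frame with strictly more peaks than this is a
#'   hit (default 15).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(window = 32L, snr_threshold = 6,
                        max_peaks = 1024L, min_peaks_for_hit = 15L) {
  stopifnot(window >= 4L, snr_threshold > 0, max_peaks >= 1L)
  structure(list(window = as.integer(window), snr_threshold = snr_threshold,
                 max_peaks = as.integer(max_peaks),
                 min_peaks_for_hit = as.integer(min_peaks_for_hit)),
            class = "peak_config")
}

# Clipped square window of edge `w` centered at (r, c): rows r-(h-1)..r+(w-h)
# with h = floor(w/2), clipped to the image.
window_bounds <- function(r, c, w, nr, nc) {
  h <- w %/% 2L
  list(r0 = max(1L, r - (h - 1L)), r1 = min(nr, r + (w - h)),
       c0 = max(1L, c - (h - 1L)), c1 = min(nc, c + (w - h)))
}

#' Candidate Bragg-peak pixels
#'
#' A valid pixel is a candidate if it is a strict maximum of its 3x3
#' neighbourhood and exceeds the median of the valid pixels in its local
#' window — the cheap first-pass threshold, later refined per candidate by
#' the robust local background model.
#'
#' @param image Numeric matrix of detector counts.
#' @param mask Optional logical matrix, `TRUE` = usable pixel.
#' @param config A [peak_config()].
#' @return Data frame with columns `row`, `col`, `value`, sorted by
#'   intensity descending and capped at `max_peaks`. May have zero rows.
#' @export
find_candidates <- function(image, mask = NULL, config = peak_config()) {
  image <- as.matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  valid <- if (is.null(mask)) matrix(TRUE, nr, nc) else mask
  work <- image
  work[!valid] <- -Inf               # masked pixels neither seed nor block
  is_max <- valid
  for (dr in -1L:1L) {
    for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      shifted <- matrix(-Inf, nr, nc)
      rs <- max(1L, 1L + dr):min(nr, nr + dr)
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      shifted[rs, cs] <- work[rs - dr, cs - dc]
      is_max <- is_max & (work > shifted)
    }
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  }
  keep <- logical(nrow(cand))
  w <- config$window
  for (i in seq_len(nrow(cand))) {
    b <- window_bounds(cand[i, 1L], cand[i, 2L], w, nr, nc)
    px <- image[b$r0:b$r1, b$c0:b$c1]
    vm <- valid[b$r0:b$r1, b$c0:b$c1]
    keep[i] <- image[cand[i, 1L], cand[i, 2L]] > median(px[vm])
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  ord <- head(ord, config$max_peaks)
  data.frame(row = as.integer(cand[ord, 1L]),
             col = as.integer(cand[ord, 2L]),
             value = vals[ord])
}

#' Robust local background and SNR of one candidate pixel
#'
#' Fits a tilted plane robustly to the candidate's local window and returns
#' the candidate's SNR against the plane prediction at the seed and the
#' window's robust noise scale. This replaces the crude median threshold of
#' [find_candidates()] with an accurate local background model.
#'
#' @param image,mask As in [find_candidates()].
#' @param seed Integer vector `c(row, col)` of the candidate pixel.
#' @param config A [peak_config()].
#' @param flkos_cfg,msse_cfg Fitting configurations.
#' @return A list: `ok` (logical), and when `ok`, `snr` and `model`
#'   (plane coefficients `a`, `b`, `c`, the scale `sigma` and the window
#'   bounds). When not `ok`, `reason` explains the discard.
#' @export
evaluate_candidate <- function(image, seed, mask = NULL,
                               config = peak_config(),
                               flkos_cfg = flkos_config(),
                               msse_cfg = msse_config()) {
  image <- as.matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  valid <- if (is.null(mask)) matrix(TRUE, nr, nc) else mask
  b <- window_bounds(seed[1L], seed[2L], config$window, nr, nc)
  vm <- valid[b$r0:b$r1, b$c0:b$c1, drop = FALSE]
  nv <- sum(vm)
  if (nv < msse_cfg$k_min + 1L) {
    return(list(ok = FALSE,
                reason = sprintf("window has %d valid pixels (< k_min + 1)",
                                 nv)))
  }
  idx <- which(vm, arr.ind = TRUE)
  px <- (b$c0:b$c1)[idx[, 2L]]
  py <- (b$r0:b$r1)[idx[, 1L]]
  vals <- image[b$r0:b$r1, b$c0:b$c1, drop = FALSE][vm]
  fit <- tryCatch(fit_plane(px, py, vals, flkos_cfg, msse_cfg),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ok = FALSE, reason = "degenerate window geometry"))
  }
  mu <- predict(fit, seed[2L], seed[1L])
  sig <- max(fit$sigma, msse_cfg$minimum_residual)
  xv <- image[seed[1L], seed[2L]]
  s <- if (sig > 0) {
    snr(xv, mu, sig)
  } else if (xv == mu) 0 else sign(xv - mu) * Inf
  list(ok = TRUE, snr = as.numeric(s),
       model = list(a = fit$params[["a"]], b = fit$params[["b"]],
                    c = fit$params[["c"]], sigma = fit$sigma, bounds = b))
}

plane_pred <- function(model, row, col) {
  model$a * col + model$b * row + model$c
}

#' Grow a peak from an accepted seed
#'
#' 4-connected flood fill from the seed over valid, unclaimed pixels whose
#' intensity exceeds the local background plane prediction; growth is
#' confined to the seed's window. Returns the peak's intensity-weighted
#' centroid (weights are the background-subtracted intensities) and its
#' background-subtracted total intensity.
#'
#' @param image Numeric matrix.
#' @param seed `c(row, col)` of the accepted candidate.
#' @param model Local background model from [evaluate_candidate()].
#' @param claimed Optional logical matrix of pixels already owned by other
#'   peaks (or masked); claimed pixels never join.
#' @return A list: `seed_row`, `seed_col`, `centroid_row`, `centroid_col`,
#'   `n_pixels`, `total_intensity`, and `members` (matrix of member
#'   `row`/`col`).
#' @export
grow_peak <- function(image, seed, model, claimed = NULL) {
  image <- as.matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  if (is.null(claimed)) claimed <- matrix(FALSE, nr, nc)
  b <- model$bounds
  members <- matrix(integer(), 0L, 2L)
  queue <- matrix(as.integer(seed), 1L, 2L)
  seen <- claimed
  seen[seed[1L], seed[2L]] <- TRUE
  while (nrow(queue) > 0L) {
    pt <- queue[1L, ]
    queue <- queue[-1L, , drop = FALSE]
    members <- rbind(members, pt)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- pt[1L] + d[1L]
      c <- pt[2L] + d[2L]
      if (r < b$r0 || r > b$r1 || c < b$c0 || c > b$c1) next
      if (seen[r, c]) next
      seen[r, c] <- TRUE
      pred <- plane_pred(model, r, c)
      # strict "above background", with a relative guard so an exactly
      # representable plane does not admit its own pixels via rounding dust
      if (image[r, c] - pred > 1e-8 * max(1, abs(pred))) {
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  bg <- plane_pred(model, members[, 1L], members[, 2L])
  excess <- pmax(image[members] - bg, 0)
  wsum <- sum(excess)
  if (wsum <= 0) {
    cr <- as.numeric(seed[1L])
    cc <- as.numeric(seed[2L])
  } else {
    cr <- sum(members[, 1L] * excess) / wsum
    cc <- sum(members[, 2L] * excess) / wsum
  }
  list(seed_row = as.integer(seed[1L]), seed_col = as.integer(seed[2L]),
       centroid_row = cr, centroid_col = cc,
       n_pixels = nrow(members),
       total_intensity = sum(image[members] - bg),
       members = unname(members))
}

#' Robust Bragg-peak detection in one detector frame
#'
#' The three-step robust peak finder: (i) candidate pixels are strict local
#' maxima above their window median; (ii) each candidate's local background
#' is modelled by a robust tilted plane and the candidate's SNR computed
#' against it; (iii) candidates with SNR at or above the threshold are grown
#' into peaks by flood fill above the background plane. Grown pixels are
#' claimed, so peak membership is a partition and at most one peak per
#' connected spot is produced.
#'
#' @inheritParams find_candidates
#' @param flkos_cfg,msse_cfg Fitting configurations for the window fits.
#' @return A data frame of class `peak_list` with one row per peak:
#'   `seed_row`, `seed_col`, `centroid_row`, `centroid_col`, `n_pixels`,
#'   `total_intensity`, `snr`. Coordinates are 1-based (row, col).
#' @export
find_peaks <- function(image, mask = NULL, config = peak_config(),
                       flkos_cfg = flkos_config(),
                       msse_cfg = msse_config()) {
  image <- as.matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  valid <- if (is.null(mask)) matrix(TRUE, nr, nc) else mask
  cand <- find_candidates(image, mask, config)
  claimed <- !valid
  rows <- vector("list", nrow(cand))
  np <- 0L
  for (i in seq_len(nrow(cand))) {
    r <- cand$row[i]
    c <- cand$col[i]
    if (claimed[r, c]) next
    ev <- evaluate_candidate(image, c(r, c), mask, config,
                             flkos_cfg, msse_cfg)
    if (!ev$ok) next
    if (ev$snr < config$snr_threshold) next
    pk <- grow_peak(image, c(r, c), ev$model, claimed)
    claimed[pk$members] <- TRUE
    np <- np + 1L
    rows[[np]] <- data.frame(seed_row = pk$seed_row, seed_col = pk$seed_col,
                             centroid_row = pk$centroid_row,
                             centroid_col = pk$centroid_col,
                             n_pixels = pk$n_pixels,
                             total_intensity = pk$total_intensity,
                             snr = ev$snr)
  }
  out <- if (np > 0L) {
    do.call(rbind, rows[seq_len(np)])
  } else {
    data.frame(seed_row = integer(), seed_col = integer(),
               centroid_row = numeric(), centroid_col = numeric(),
               n_pixels = integer(), total_intensity = numeric(),
               snr = numeric())
  }
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Hit classification from a peak list
#'
#' A frame is a hit when it contains strictly more peaks than
#' `min_peaks_for_hit`.
#'
#' @param peaks A `peak_list` (or any data frame of peaks).
#' @param min_peaks_for_hit Count threshold.
#' @return Logical scalar.
#' @export
is_hit <- function(peaks, min_peaks_for_hit = 15L) {
  nrow(peaks) > min_peaks_for_hit
}
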