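#' Per-pixel temporal feature maps of a calibration frame stack
#'
#' Computes plain (non-robust) per-pixel statistics over the frames of a
#' dark-field or near-flat bright-field acquisition. Non-robust on purpose:
#' an abnormal pixel should bias its own feature so the robust windowed
#' model can expose it later.
#'
#' @param stack 3D numeric array, `rows x cols x n_frames`.
#' @param features Character vector of feature names; any subset of the
#'   registry returned by [feature_registry()].
#' @return Named list of matrices (one per feature).
#' @export
#' @examples
#' st <- gen_frame_stack(shape = c(64, 64), n_frames = 20, seed = 1)
#' fm <- compute_feature_maps(st$stack)
#' names(fm)
compute_feature_maps <- function(stack,
                                 features = c("temporal_mean",
                                              "temporal_std")) {
  stopifnot(length(dim(stack)) == 3L)
  if (dim(stack)[3L] < 2L) stop("need at least 2 frames")
  reg <- feature_registry()
  unknown <- setdiff(features, names(reg))
  if (length(unknown) > 0L) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  out <- lapply(features, function(f) reg[[f]](stack))
  names(out) <- features
  out
}

#' Registry of per-pixel temporal features
#'
#' Extensible: each entry maps a `rows x cols x n_frames` array to a
#' `rows x cols` matrix. The published mask-making pipeline names only the
#' temporal average explicitly; mean, standard deviation, median and range
#' are provided here and further statistics can be added by the caller.
#'
#' @return Named list of functions.
#' @export
feature_registry <- function() {
  list(
    temporal_mean = function(stack) rowMeans(stack, dims = 2L),
    temporal_std = function(stack) {
      n <- dim(stack)[3L]
      m <- rowMeans(stack, dims = 2L)
      s2 <- (rowSums(stack^2, dims = 2L) - n * m^2) / (n - 1L)
      sqrt(pmax(s2, 0))
    },
    temporal_median = function(stack) apply(stack, c(1L, 2L), median),
    temporal_range = function(stack) {
      apply(stack, c(1L, 2L), function(v) diff(range(v)))
    }
  )
}

#' Abnormality (SNR) map of a per-pixel feature
#'
#' Models normal pixel behaviour robustly within square windows of the
#' feature map (a windowed robust constant, the `num_model_params = 1`
#' background machinery) and returns each pixel's signed SNR against its
#' window model. Hot pixels come out strongly positive, dead pixels
#' strongly negative.
#'
#' @param feature Matrix, one per-pixel statistic (e.g. from
#'   [compute_feature_maps()]).
#' @param win Window edge in pixels (default 64).
#' @param mask Optional logical validity matrix.
#' @param flkos_cfg,msse_cfg Fitting configurations.
#' @return Matrix of signed SNR values, same shape as `feature`. Pixels in
#'   windows with exactly zero spread and zero deviation get SNR 0.
#' @export
abnormality_map <- function(feature, win = 64L, mask = NULL,
                            flkos_cfg = flkos_config(),
                            msse_cfg = msse_config()) {
  feature <- as.matrix(feature)
  bg <- fit_background(feature, mask,
                       background_config(win_x = win, win_y = win,
                                         num_model_params = 1L),
                       flkos_cfg, msse_cfg)
  diff <- feature - bg$mean
  sig <- pmax(bg$scale, msse_cfg$minimum_residual)
  out <- matrix(NA_real_, nrow(feature), ncol(feature))
  pos <- !is.na(sig) & sig > 0
  out[pos] <- diff[pos] / sig[pos]
  zero <- !is.na(sig) & sig == 0
  out[zero] <- ifelse(diff[zero] == 0, 0, sign(diff[zero]) * Inf)
  out
}

#' Build a coded bad-pixel mask from a calibration frame stack
#'
#' For each selected feature, pixels whose abnormality SNR exceeds the
#' threshold in absolute value get that feature's bit set in an 8-bit code;
#' code 0 means a good pixel. A derived "dead" bit is additionally set for
#' pixels whose temporal standard deviation *and* temporal mean are both
#' far below the model (constant, silent pixels), when both features are
#' selected.
#'
#' @param stack 3D array `rows x cols x n_frames`.
#' @param features Feature names (at most 8 including the derived dead
#'   class); default `temporal_mean` and `temporal_std`.
#' @param threshold SNR threshold (default 6); masking is two-sided on
#'   `|SNR|`.
#' @param win Window edge for the robust normal-behaviour model
#'   (default 64).
#' @param mask Optional validity matrix.
#' @param flkos_cfg,msse_cfg Fitting configurations.
#' @return An integer matrix of class `bad_pixel_mask` with values in
#'   0..255; attributes `bits` (bit value per class) and `counts` (pixels
#'   flagged per class).
#' @export
make_mask <- function(stack, features = c("temporal_mean", "temporal_std"),
                      threshold = 6, win = 64L, mask = NULL,
                      flkos_cfg = flkos_config(),
                      msse_cfg = msse_config()) {
  has_dead <- all(c("temporal_mean", "temporal_std") %in% features)
  n_classes <- length(features) + as.integer(has_dead)
  if (n_classes > 8L) {
    stop("at most 8 defect classes fit the 8-bit code budget; got ",
         n_classes)
  }
  fmaps <- compute_feature_maps(stack, features)
  amaps <- lapply(fmaps, abnormality_map, win = win, mask = mask,
                  flkos_cfg = flkos_cfg, msse_cfg = msse_cfg)
  codes <- matrix(0L, dim(stack)[1L], dim(stack)[2L])
  bits <- integer(0)
  counts <- integer(0)
  for (i in seq_along(features)) {
    bit <- bitwShiftL(1L, i - 1L)
    bad <- !is.na(amaps[[i]]) & abs(amaps[[i]]) >= threshold
    codes[bad] <- bitwOr(codes[bad], bit)
    bits[features[i]] <- bit
    counts[features[i]] <- sum(bad)
  }
  if (has_dead) {
    bit <- bitwShiftL(1L, length(features))
    am <- amaps[["temporal_mean"]]
    as_ <- amaps[["temporal_std"]]
    bad <- !is.na(am) & !is.na(as_) &
      am <= -threshold & as_ <= -threshold
    codes[bad] <- bitwOr(codes[bad], bit)
    bits[["dead"]] <- bit
    counts[["dead"]] <- sum(bad)
  }
  structure(codes, class = c("bad_pixel_mask", class(codes)),
            bits = bits, counts = counts, threshold = threshold, win = win)
}

#' @export
print.bad_pixel_mask <- function(x, ...) {
  cat("Bad-pixel mask:", nrow(x), "x", ncol(x), "pixels,",
      sum(x > 0L), "flagged\n")
  cnt <- attr(x, "counts")
  for (nm in names(cnt)) cat(sprintf("  %-14s (bit %d): %d\n", nm,
                                     attr(x, "bits")[[nm]], cnt[[nm]]))
  invisible(x)
}
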