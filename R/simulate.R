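#' Synthetic 1D dataset: Gaussian inliers plus uniform outliers
#'
#' The canonical robust-fitting demo: `ceiling(inlier_frac * n)` draws from
#' `N(mu, sigma^2)` plus uniform outliers on `[outlier_low, outlier_high]`,
#' shuffled under the seed. Labels follow the generator, not the value: an
#' outlier draw landing inside the inlier band keeps its outlier label.
#'
#' @param n Total number of points.
#' @param inlier_frac Fraction of inliers (default 0.7).
#' @param mu,sigma Inlier Gaussian mean and standard deviation.
#' @param outlier_low,outlier_high Uniform outlier range (defaults 1.5 and
#'   6.5).
#' @param seed RNG seed; regeneration is bit-identical.
#' @return A list: `data` (numeric vector), `truth` (list with `is_inlier`
#'   labels aligned to `data`, the planted parameters and the seed).
#' @export
#' @examples
#' d <- gen_1d_dataset(100, seed = 7)
#' sum(d$truth$is_inlier)   # 70
gen_1d_dataset <- function(n, inlier_frac = 0.7, mu = 0, sigma = 0.5,
                           outlier_low = 1.5, outlier_high = 6.5,
                           seed = 1L) {
  stopifnot(n >= 1, inlier_frac >= 0, inlier_frac <= 1)
  n_in <- as.integer(ceiling(inlier_frac * n))
  n_out <- n - n_in
  with_seed(seed, {
    x <- c(rnorm(n_in, mu, sigma), runif(n_out, outlier_low, outlier_high))
    lab <- rep(c(TRUE, FALSE), c(n_in, n_out))
    perm <- sample.int(n)
    list(data = x[perm],
         truth = list(is_inlier = lab[perm], mu = mu, sigma = sigma,
                      n_inliers = n_in, n_outliers = n_out,
                      outlier_range = c(outlier_low, outlier_high),
                      seed = seed))
  })
}

#' Synthetic 2D line dataset
#'
#' Inliers on `y = intercept + slope * x` with vertical Gaussian noise;
#' outliers uniform in the bounding box.
#'
#' @param n Total points.
#' @param slope,intercept Planted line.
#' @param sigma Inlier noise standard deviation.
#' @param outlier_frac Fraction of outliers (default 0.3).
#' @param bbox `c(xmin, xmax, ymin, ymax)` for x sampling and outliers.
#' @param seed RNG seed.
#' @return A list: `x`, `y`, `truth` (labels and planted parameters).
#' @export
gen_line_dataset <- function(n, slope = 2, intercept = 1, sigma = 0.25,
                             outlier_frac = 0.3,
                             bbox = c(-5, 5, -12, 12), seed = 1L) {
  n_out <- as.integer(floor(outlier_frac * n))
  n_in <- n - n_out
  with_seed(seed, {
    xi <- runif(n_in, bbox[1L], bbox[2L])
    yi <- intercept + slope * xi + rnorm(n_in, 0, sigma)
    xo <- runif(n_out, bbox[1L], bbox[2L])
    yo <- runif(n_out, bbox[3L], bbox[4L])
    lab <- rep(c(TRUE, FALSE), c(n_in, n_out))
    perm <- sample.int(n)
    list(x = c(xi, xo)[perm], y = c(yi, yo)[perm],
         truth = list(is_inlier = lab[perm], slope = slope,
                      intercept = intercept, sigma = sigma,
                      n_inliers = n_in, n_outliers = n_out, seed = seed))
  })
}

#' Synthetic gridded plane dataset with boosted outlier pixels
#'
#' A plane `z = a*x + b*y + c` sampled on a grid with Gaussian noise;
#' a random fraction of pixels is boosted by `boost` (a planted "peak").
#'
#' @param grid_shape `c(rows, cols)` of the grid (default 32 x 32).
#' @param a,b,c Planted plane coefficients (`x` is the column index, `y`
#'   the row index).
#' @param sigma Noise standard deviation.
#' @param outlier_frac Fraction of boosted pixels (default 0.1).
#' @param boost Intensity added to outlier pixels (default 40).
#' @param seed RNG seed.
#' @return A list: `x`, `y`, `z` vectors, `truth` with labels.
#' @export
gen_plane_dataset <- function(grid_shape = c(32L, 32L), a = 0.1, b = 0.2,
                              c = 50, sigma = 2, outlier_frac = 0.1,
                              boost = 40, seed = 1L) {
  nr <- grid_shape[1L]
  nc <- grid_shape[2L]
  n <- nr * nc
  gy <- rep(seq_len(nr), times = nc)
  gx <- rep(seq_len(nc), each = nr)
  with_seed(seed, {
    z <- a * gx + b * gy + c + rnorm(n, 0, sigma)
    n_out <- as.integer(round(outlier_frac * n))
    out_idx <- sample.int(n, n_out)
    z[out_idx] <- z[out_idx] + boost
    lab <- rep(TRUE, n)
    lab[out_idx] <- FALSE
    list(x = gx, y = gy, z = z,
         truth = list(is_inlier = lab, a = a, b = b, c = c, sigma = sigma,
                      boost = boost, n_outliers = n_out, seed = seed))
  })
}

#' Synthetic diffraction pattern: tilted background, noise, Gaussian spots
#'
#' A tilted-plane background plus i.i.d. Gaussian noise plus 2D Gaussian
#' Bragg-peak spots at planted positions. The truth records each spot's
#' centre and nominal SNR (`amplitude / noise_sigma`).
#'
#' @param shape `c(rows, cols)` (default 256 x 256).
#' @param bg_plane `c(a, b, c)`: background `a*col + b*row + c`. The
#'   default gradient is gentle so spot apices dominate the frame's upper
#'   intensity range.
#' @param noise_sigma Background noise standard deviation (default 3).
#' @param peaks Data frame or matrix with columns `row`, `col`,
#'   `amplitude`, `width` (Gaussian sigma in pixels). `NULL` plants a
#'   default set of 10 well-separated strong spots.
#' @param n_peaks,amplitude,width Used only when `peaks` is `NULL`:
#'   number of default spots and their shared amplitude/width.
#' @param seed RNG seed.
#' @return A list: `image` (matrix), `truth` (peak table with nominal SNR,
#'   background parameters, seed).
#' @export
gen_diffraction_pattern <- function(shape = c(256L, 256L),
                                    bg_plane = c(0.02, 0.03, 50),
                                    noise_sigma = 3, peaks = NULL,
                                    n_peaks = 10L, amplitude = NULL,
                                    width = 2, seed = 1L) {
  nr <- shape[1L]
  nc <- shape[2L]
  if (is.null(peaks)) {
    amplitude <- amplitude %||% (10 * noise_sigma)
    if (n_peaks > 0L) {
      # deterministic, well-separated grid placement away from the edges
      gs <- ceiling(sqrt(n_peaks))
      rr <- round(seq(0.15, 0.85, length.out = gs) * nr)
      cc <- round(seq(0.15, 0.85, length.out = gs) * nc)
      pos <- expand.grid(row = rr, col = cc)[seq_len(n_peaks), ]
      peaks <- data.frame(row = pos$row, col = pos$col,
                          amplitude = amplitude, width = width)
    } else {
      peaks <- data.frame(row = integer(), col = integer(),
                          amplitude = numeric(), width = numeric())
    }
  }
  peaks <- as.data.frame(peaks)
  img <- with_seed(seed, {
    m <- outer(seq_len(nr), seq_len(nc),
               function(r, c) bg_plane[1L] * c + bg_plane[2L] * r +
                 bg_plane[3L])
    if (noise_sigma > 0) m <- m + matrix(rnorm(nr * nc, 0, noise_sigma),
                                         nr, nc)
    m
  })
  for (i in seq_len(nrow(peaks))) {
    r0 <- peaks$row[i]
    c0 <- peaks$col[i]
    w <- peaks$width[i]
    ext <- ceiling(4 * w)
    rs <- max(1L, r0 - ext):min(nr, r0 + ext)
    cs <- max(1L, c0 - ext):min(nc, c0 + ext)
    spot <- peaks$amplitude[i] *
      exp(-(outer((rs - r0)^2, (cs - c0)^2, "+")) / (2 * w^2))
    img[rs, cs] <- img[rs, cs] + spot
  }
  truth <- peaks
  truth$nominal_snr <- if (noise_sigma > 0) {
    peaks$amplitude / noise_sigma
  } else {
    Inf
  }
  list(image = img,
       truth = list(peaks = truth, bg_plane = bg_plane,
                    noise_sigma = noise_sigma, seed = seed))
}

#' Synthetic calibration frame stack with planted defective pixels
#'
#' I.i.d. Gaussian frames around a flat base level (a dark-field or
#' near-flat bright-field acquisition where all healthy pixels behave
#' alike), with planted hot pixels (mean offset), dead pixels (constant 0)
#' and flickering pixels (inflated temporal standard deviation).
#'
#' @param shape `c(rows, cols)` (default 512 x 512).
#' @param n_frames Number of frames (default 100).
#' @param base_level Healthy-pixel mean (default 100 counts).
#' @param noise_sigma Healthy-pixel temporal standard deviation (default 5).
#' @param n_hot,hot_offset Hot pixels: count (default 30) and mean offset
#'   (default 50, i.e. 10 noise sigmas).
#' @param n_dead Dead pixels, constant 0 (default 10).
#' @param n_flicker,flicker_factor Flickering pixels: count (default 20)
#'   and std inflation factor (default 3).
#' @param seed RNG seed.
#' @return A list: `stack` (`rows x cols x n_frames` array), `truth`
#'   (defect coordinate tables and planted parameters).
#' @export
gen_frame_stack <- function(shape = c(512L, 512L), n_frames = 100L,
                            base_level = 100, noise_sigma = 5,
                            n_hot = 30L, hot_offset = 50,
                            n_dead = 10L, n_flicker = 20L,
                            flicker_factor = 3, seed = 1L) {
  nr <- shape[1L]
  nc <- shape[2L]
  npix <- nr * nc
  with_seed(seed, {
    stack <- array(rnorm(npix * n_frames, base_level, noise_sigma),
                   dim = c(nr, nc, n_frames))
    n_def <- n_hot + n_dead + n_flicker
    def <- sample.int(npix, n_def)
    hot <- def[seq_len(n_hot)]
    dead <- def[n_hot + seq_len(n_dead)]
    flick <- def[n_hot + n_dead + seq_len(n_flicker)]
    for (f in seq_len(n_frames)) {
      sl <- (f - 1L) * npix
      stack[sl + hot] <- stack[sl + hot] + hot_offset
      stack[sl + dead] <- 0
      stack[sl + flick] <- base_level +
        rnorm(n_flicker, 0, noise_sigma * flicker_factor)
    }
    coords <- function(idx) {
      cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
    }
    list(stack = stack,
         truth = list(hot = coords(hot), dead = coords(dead),
                      flicker = coords(flick), base_level = base_level,
                      noise_sigma = noise_sigma, hot_offset = hot_offset,
                      flicker_factor = flicker_factor, seed = seed))
  })
}
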