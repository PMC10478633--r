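#' Background estimation configuration
#'
#' @param win_x,win_y Window extents in pixels (columns, rows). `NULL`
#'   (default) means the full image extent, i.e. a single window.
#' @param num_model_params 4 (default) fits a tiltable plane — three plane
#'   parameters plus the noise scale — per window; 1 fits a horizontal
#'   plane (a robust constant) per window.
#' @param num_strides Number of stride offsets per axis (default 1, the
#'   plain tiling). Offsets are `round(i * win / num_strides)` for
#'   `i = 0 .. num_strides - 1`; per-pixel results are averaged across the
#'   shifted tilings.
#' @param minimum_residual Optional override of the MSSE residual floor for
#'   the window fits.
#' @return A list of class `background_config`.
#' @export
background_config <- function(win_x = NULL, win_y = NULL,
                              num_model_params = 4L, num_strides = 1L,
                              minimum_residual = NULL) {
  num_model_params <- as.integer(num_model_params)
  if (!num_model_params %in% c(1L, 4L)) {
    stop("`num_model_params` must be 1 (horizontal plane) or 4 ",
         "(tiltable plane + scale)")
  }
  stopifnot(num_strides >= 1L)
  structure(list(win_x = win_x, win_y = win_y,
                 num_model_params = num_model_params,
                 num_strides = as.integer(num_strides),
                 minimum_residual = minimum_residual),
            class = "background_config")
}

# Window start/end rows (or cols) for one stride offset; the clipped head
# window [1, off] is kept so every pixel is covered in every stride layer.
stride_bounds <- function(off, win, n) {
  st <- seq.int(off + 1L, n, by = win)
  if (off > 0L) st <- c(1L, st)
  st <- st[st <= n]
  cbind(start = st, end = c(st[-1L] - 1L, n))
}

#' Per-pixel robust background mean and scale maps
#'
#' Tiles a detector image with windows, robustly fits each window with a
#' tilted plane ([fit_plane()]) or a constant ([fit_value()]), writes the
#' model prediction and the window's noise scale to every covered pixel,
#' and averages across `num_strides` shifted tilings. Pixels excluded by
#' `mask` never influence any fit and carry `NA` in the output maps.
#'
#' @param image Numeric matrix of detector counts (rows x cols).
#' @param mask Optional logical matrix, `TRUE` = usable pixel.
#' @param config A [background_config()].
#' @param flkos_cfg A [flkos_config()] for the window fits.
#' @param msse_cfg An [msse_config()].
#' @return A list of class `background_maps` with matrices `mean` and
#'   `scale`, the same shape as `image`.
#' @export
fit_background <- function(image, mask = NULL,
                           config = background_config(),
                           flkos_cfg = flkos_config(),
                           msse_cfg = msse_config()) {
  image <- as.matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  valid <- if (is.null(mask)) {
    matrix(TRUE, nr, nc)
  } else {
    stopifnot(identical(dim(mask), dim(image)))
    mask & is.finite(image)
  }
  if (!all(is.finite(image[valid]))) stop("non-finite values on valid pixels")
  if (!is.null(config$minimum_residual)) {
    msse_cfg$minimum_residual <- config$minimum_residual
  }
  win_y <- as.integer(config$win_y %||% nr)
  win_x <- as.integer(config$win_x %||% nc)
  ns <- config$num_strides
  kmin <- msse_cfg$k_min

  sum_m <- matrix(0, nr, nc)
  sum_s <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  n_fitted <- 0L

  offs_y <- unique(as.integer(round((seq_len(ns) - 1L) * win_y / ns)))
  offs_x <- unique(as.integer(round((seq_len(ns) - 1L) * win_x / ns)))
  for (oy in offs_y) {
    rb <- stride_bounds(oy, win_y, nr)
    for (ox in offs_x) {
      cb <- stride_bounds(ox, win_x, nc)
      for (i in seq_len(nrow(rb))) {
        rows <- rb[i, "start"]:rb[i, "end"]
        for (j in seq_len(nrow(cb))) {
          cols <- cb[j, "start"]:cb[j, "end"]
          vm <- valid[rows, cols, drop = FALSE]
          nv <- sum(vm)
          if (nv < kmin + 1L) next
          vals <- image[rows, cols, drop = FALSE][vm]
          idx <- which(vm, arr.ind = TRUE)
          fit <- tryCatch({
            if (config$num_model_params == 4L) {
              px <- cols[idx[, 2L]]
              py <- rows[idx[, 1L]]
              f <- fit_plane(px, py, vals, flkos_cfg, msse_cfg)
              list(pred = predict(f, px, py), sigma = f$sigma)
            } else {
              f <- fit_value(vals, flkos_cfg, msse_cfg)
              list(pred = rep(f$params[["value"]], nv), sigma = f$sigma)
            }
          }, error = function(e) NULL)
          if (is.null(fit)) next    # degenerate window (e.g. 1-pixel strip)
          rr <- rows[idx[, 1L]]
          cc <- cols[idx[, 2L]]
          lin <- rr + (cc - 1L) * nr
          sum_m[lin] <- sum_m[lin] + fit$pred
          sum_s[lin] <- sum_s[lin] + fit$sigma
          cnt[lin] <- cnt[lin] + 1L
          n_fitted <- n_fitted + 1L
        }
      }
    }
  }
  if (n_fitted == 0L) {
    stop("no window holds at least k_min + 1 = ", kmin + 1L,
         " usable pixels; enlarge the window or relax the mask")
  }
  mean_map <- sum_m / cnt
  scale_map <- sum_s / cnt
  # Pixels in windows that were too masked/degenerate to fit fall back to
  # the nearest fitted pixel's model value.
  unc <- which(cnt == 0L & valid, arr.ind = TRUE)
  if (nrow(unc) > 0L) {
    cov <- which(cnt > 0L, arr.ind = TRUE)
    for (i in seq_len(nrow(unc))) {
      d2 <- (cov[, 1L] - unc[i, 1L])^2 + (cov[, 2L] - unc[i, 2L])^2
      jj <- which.min(d2)
      mean_map[unc[i, 1L], unc[i, 2L]] <- mean_map[cov[jj, 1L], cov[jj, 2L]]
      scale_map[unc[i, 1L], unc[i, 2L]] <- scale_map[cov[jj, 1L], cov[jj, 2L]]
    }
  }
  mean_map[!valid] <- NA_real_
  scale_map[!valid] <- NA_real_
  structure(list(mean = mean_map, scale = scale_map),
            class = "background_maps")
}

#' @export
print.background_maps <- function(x, ...) {
  cat("Background maps:", nrow(x$mean), "x", ncol(x$mean), "pixels\n")
  cat("  mean  range:", paste(format(range(x$mean, na.rm = TRUE),
                                     digits = 6), collapse = " .. "), "\n")
  cat("  scale range:", paste(format(range(x$scale, na.rm = TRUE),
                                     digits = 6), collapse = " .. "), "\n")
  invisible(x)
}
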