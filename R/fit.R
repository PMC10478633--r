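#' FLkOS optimizer configuration
#'
#' Tuning constants of the fast least-kth-order-statistics (FLkOS) guided
#' sampling optimizer behind all robust fitters.
#'
#' @param likely_ratio Fraction of the data assumed to belong to the target
#'   structure (default 0.5). The optimizer minimizes the residual of the
#'   `k = ceiling(likely_ratio * N)`-th order statistic. In windowed image
#'   work this encodes "at least half the pixels in any reasonable window
#'   are background".
#' @param certain_ratio Fraction of the data highly likely to be inliers
#'   (default 0.3); sets the size of the fitted subset, a block of ranks
#'   ending at `k`.
#' @param opt_iters Iteration budget (default 12).
#' @param fit2skewed If `TRUE`, `certain_ratio` decays linearly to 0.05
#'   across the iterations, which lets the fitted block slide toward the
#'   mode of a skewed (e.g. Poisson-convolved) density.
#' @param downsampled_size Optional subsample size: the fit runs on a seeded
#'   uniform subsample without replacement and inlier flags are then
#'   computed for all points. Values `>= N` disable downsampling.
#' @param model_value_init Optional initial model parameters (a scalar for
#'   value fits, length-2 for lines, length-3 for planes). When given, the
#'   first subset comes from the residual ranking under this model instead
#'   of a random sample.
#' @param rng_seed Seed controlling all sampling (default 1). Fits are
#'   bit-reproducible for a fixed seed.
#'
#' @return A list of class `flkos_config`.
#' @export
flkos_config <- function(likely_ratio = 0.5, certain_ratio = 0.3,
                         opt_iters = 12L, fit2skewed = FALSE,
                         downsampled_size = NULL, model_value_init = NULL,
                         rng_seed = 1L) {
  stopifnot(certain_ratio > 0, certain_ratio <= likely_ratio,
            likely_ratio <= 1, opt_iters >= 1)
  structure(list(likely_ratio = likely_ratio, certain_ratio = certain_ratio,
                 opt_iters = as.integer(opt_iters),
                 fit2skewed = isTRUE(fit2skewed),
                 downsampled_size = downsampled_size,
                 model_value_init = model_value_init,
                 rng_seed = as.integer(rng_seed)),
            class = "flkos_config")
}

# Shared FLkOS driver. X is the N x p design matrix, y the response.
# Returns a bare list (coef, residuals); callers wrap into rgf_fit.
flkos_engine <- function(X, y, config, msse_cfg, check_rank = TRUE) {
  N <- length(y)
  p <- ncol(X)
  if (N < msse_cfg$k_min + 1L) {
    stop("need at least k_min + 1 = ", msse_cfg$k_min + 1L,
         " points, got ", N)
  }
  if (!all(is.finite(y)) || !all(is.finite(X))) {
    stop("points must be finite")
  }
  if (check_rank && qr(X)$rank < p) {
    stop("rank-deficient design: the ", p, "-parameter model is not ",
         "identifiable from these points (degenerate geometry)")
  }
  k <- ceiling(config$likely_ratio * N)
  k <- min(max(k, p + 1L), N)
  cr <- if (config$fit2skewed && config$opt_iters > 1L) {
    seq(config$certain_ratio, 0.05, length.out = config$opt_iters)
  } else {
    rep(config$certain_ratio, config$opt_iters)
  }
  s_sched <- pmin(pmax(p + 1L, ceiling(cr * N)), k)
  init <- config$model_value_init
  subset0 <- if (!is.null(init)) {
    if (length(init) != p) {
      stop("`model_value_init` must have length ", p, " for this model")
    }
    r2 <- as.numeric((y - X %*% init)^2)
    ord <- order(r2)
    ord[(k - s_sched[1L] + 1L):k]
  } else {
    with_seed(config$rng_seed, sample.int(N, s_sched[1L]))
  }
  fit <- cpp_flkos(X, y, as.integer(subset0) - 1L, as.integer(k),
                   as.integer(s_sched))
  # By assumption certain_ratio * N points are highly likely to be inliers,
  # so the MSSE scan inside the fitters may start there instead of at the
  # global k_min floor; this prevents chance lock-in on a tight cluster of
  # a dozen residuals in large windows.
  k_certain <- min(as.integer(ceiling(config$certain_ratio * N)), k)
  list(coef = as.numeric(fit$coef), residuals = as.numeric(fit$residuals),
       k_certain = k_certain)
}

# Threshold-rule inlier flags: |r| (floored) <= lambda * sigma (floored).
flag_inliers <- function(residuals, sigma, msse_cfg) {
  mr <- msse_cfg$minimum_residual
  thr <- msse_cfg$lambda_cutoff * max(sigma, mr)
  pmax(abs(residuals), mr) <= thr
}

# Build the fit result from the FLkOS engine output: segment inliers with
# MSSE, polish the parameters by one ordinary least-squares refit on the
# segmented inliers (the guided-sampling block alone leaves avoidable
# estimator variance), re-segment, and flag by the threshold rule.
new_rgf_fit <- function(kind, X, y, eng, par_names, msse_cfg) {
  cfg <- msse_cfg
  cfg$model_dof <- ncol(X)
  cfg$k_min <- max(cfg$k_min, eng$k_certain %||% 0L)
  est <- msse(eng$residuals^2, cfg)
  coef <- eng$coef
  residuals <- eng$residuals
  idx <- which(est$inlier_flags)
  refit <- tryCatch(qr.coef(qr(X[idx, , drop = FALSE]), y[idx]),
                    error = function(e) NULL)
  if (!is.null(refit) && all(is.finite(refit))) {
    r2 <- as.numeric(y - X %*% refit)
    est2 <- msse(r2^2, cfg)
    coef <- as.numeric(refit)
    residuals <- r2
    est <- est2
  }
  flags <- flag_inliers(residuals, est$sigma, cfg)
  params <- stats::setNames(coef, par_names)
  structure(list(kind = kind, params = params, sigma = est$sigma,
                 k_inliers = sum(flags), inlier_flags = flags,
                 threshold = cfg$lambda_cutoff * max(est$sigma,
                                                     cfg$minimum_residual),
                 residuals = residuals, n = length(residuals)),
            class = "rgf_fit")
}

#' Robust fit of a geometric model by FLkOS + MSSE
#'
#' Low-level entry point shared by [fit_value()], [fit_line()] and
#' [fit_plane()]. Iteratively least-squares-fits a block of points ranked
#' near the `k`-th order statistic of the squared residuals (guided
#' sampling), then estimates the inlier noise scale with [msse()] and flags
#' inliers at `lambda_cutoff * sigma`.
#'
#' @param points Numeric matrix of points: one column (values), two
#'   (`x`, `y`) or three (`x`, `y`, `z`); the last column is the response.
#' @param kind One of `"value"`, `"line"`, `"plane"`.
#' @param config A [flkos_config()].
#' @param msse_cfg An [msse_config()]; `model_dof` is set from `kind`.
#' @return An object of class `rgf_fit`: `params` (named model parameters),
#'   `sigma` (robust noise scale), `k_inliers`, `inlier_flags`,
#'   `threshold` (the acceptance band `lambda * sigma`) and `residuals`.
#' @export
flkos_fit <- function(points, kind = c("value", "line", "plane"),
                      config = flkos_config(), msse_cfg = msse_config()) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  switch(kind,
    value = fit_value(points[, 1L], config, msse_cfg),
    line = fit_line(points[, 1L], points[, 2L], config, msse_cfg),
    plane = fit_plane(points[, 1L], points[, 2L], points[, 3L],
                      config, msse_cfg))
}

#' Robust value (mean and scale) of a 1D data vector
#'
#' Fits a single constant to the dominant Gaussian structure of `data`,
#' ignoring outliers: the robust analogue of `mean()` plus `sd()`.
#'
#' @param data Numeric vector.
#' @param config A [flkos_config()]. `fit2skewed` and `downsampled_size`
#'   are honoured here.
#' @param msse_cfg An [msse_config()].
#' @return An `rgf_fit` with `params["value"]` the robust mean.
#' @export
#' @examples
#' x <- c(rnorm(700, 10, 2), runif(300, 40, 100))
#' fit_value(x)
fit_value <- function(data, config = flkos_config(),
                      msse_cfg = msse_config()) {
  y <- as.numeric(data)
  N <- length(y)
  ds <- config$downsampled_size
  if (!is.null(ds) && ds < N) {
    idx <- with_seed(config$rng_seed + 1L, sample.int(N, ds))
    sub_cfg <- config
    sub_cfg$downsampled_size <- NULL
    sub <- fit_value(y[idx], sub_cfg, msse_cfg)
    r <- y - sub$params[["value"]]
    flags <- flag_inliers(r, sub$sigma, msse_cfg)
    out <- sub
    out$inlier_flags <- flags
    out$k_inliers <- sum(flags)
    out$residuals <- r
    out$n <- N
    return(out)
  }
  X <- matrix(1, N, 1L)
  eng <- flkos_engine(X, y, config, msse_cfg, check_rank = FALSE)
  new_rgf_fit("value", X, y, eng, "value", msse_cfg)
}

#' Robust line fit in 2D
#'
#' Robustly fits `y = intercept + slope * x` to 2D points contaminated by
#' outliers; returns slope, intercept and the inlier noise scale.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @inheritParams fit_value
#' @return An `rgf_fit` with `params[c("slope", "intercept")]`.
#' @export
fit_line <- function(x, y, config = flkos_config(),
                     msse_cfg = msse_config()) {
  stopifnot(length(x) == length(y))
  X <- cbind(1, as.numeric(x))
  yv <- as.numeric(y)
  eng <- flkos_engine(X, yv, config, msse_cfg)
  fit <- new_rgf_fit("line", X, yv, eng, c("intercept", "slope"), msse_cfg)
  fit$params <- fit$params[c("slope", "intercept")]
  fit
}

#' Robust plane fit in 3D
#'
#' Robustly fits `z = a * x + b * y + c`; the workhorse of local background
#' modelling in diffraction images, where `x` is the column, `y` the row
#' and `z` the pixel intensity.
#'
#' @param x,y,z Numeric coordinate vectors of equal length.
#' @inheritParams fit_value
#' @return An `rgf_fit` with `params[c("a", "b", "c")]` plus `sigma`, i.e.
#'   four output parameters in total.
#' @export
fit_plane <- function(x, y, z, config = flkos_config(),
                      msse_cfg = msse_config()) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  X <- cbind(as.numeric(x), as.numeric(y), 1)
  zv <- as.numeric(z)
  eng <- flkos_engine(X, zv, config, msse_cfg)
  new_rgf_fit("plane", X, zv, eng, c("a", "b", "c"), msse_cfg)
}

#' Median of repeated robust value fits
#'
#' Runs [fit_value()] `repeats` times with derived seeds
#' (`rng_seed, rng_seed + 1, ...`) and returns the elementwise median of
#' the parameters and of the scale; inlier flags are recomputed from the
#' median model. Repetition damps the (small) sampling variability of a
#' single FLkOS run.
#'
#' @inheritParams fit_value
#' @param repeats Number of repeated fits (default 3).
#' @return An `rgf_fit`.
#' @export
median_of_fits <- function(data, config = flkos_config(),
                           msse_cfg = msse_config(), repeats = 3L) {
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1L)
  fits <- lapply(seq_len(repeats) - 1L, function(i) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i
    fit_value(data, cfg, msse_cfg)
  })
  if (repeats == 1L) return(fits[[1L]])
  med_value <- median(vapply(fits, function(f) f$params[["value"]], 0))
  med_sigma <- median(vapply(fits, function(f) f$sigma, 0))
  r <- as.numeric(data) - med_value
  flags <- flag_inliers(r, med_sigma, msse_cfg)
  structure(list(kind = "value", params = c(value = med_value),
                 sigma = med_sigma, k_inliers = sum(flags),
                 inlier_flags = flags,
                 threshold = msse_cfg$lambda_cutoff *
                   max(med_sigma, msse_cfg$minimum_residual),
                 residuals = r, n = length(r)),
            class = "rgf_fit")
}

#' Predict from a robust fit
#'
#' @param object An `rgf_fit`.
#' @param x,y Coordinates at which to evaluate the model (unused for value
#'   fits; `y` only for planes).
#' @param ... Unused.
#' @return Predicted model values.
#' @export
predict.rgf_fit <- function(object, x = NULL, y = NULL, ...) {
  p <- object$params
  switch(object$kind,
    value = rep(p[["value"]], max(1L, length(x))),
    line = p[["intercept"]] + p[["slope"]] * x,
    plane = p[["a"]] * x + p[["b"]] * y + p[["c"]])
}

#' @export
print.rgf_fit <- function(x, ...) {
  cat("Robust", x$kind, "fit (FLkOS + MSSE)\n")
  cat("  params   :", paste(names(x$params),
                            format(x$params, digits = 6),
                            sep = " = ", collapse = ", "), "\n")
  cat("  sigma    :", format(x$sigma, digits = 6), "\n")
  cat("  inliers  :", x$k_inliers, "of", x$n,
      sprintf("(threshold %.4g)", x$threshold), "\n")
  invisible(x)
}
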