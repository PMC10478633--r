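#' MSSE configuration
#'
#' Bundles the tuning constants of the modified selective statistical
#' estimator (MSSE) used throughout the package.
#'
#' @param lambda_cutoff Gaussian cutoff \eqn{\lambda} (unitless). A point is
#'   accepted as an inlier while its residual is no more than
#'   \eqn{\lambda} times the accumulated noise scale. Values between 2 and 4
#'   are customary; the default is 3.
#' @param k_min Minimum number of inliers a structure must have (default 12).
#'   Must exceed `model_dof`.
#' @param minimum_residual Floor applied to absolute residuals before
#'   squaring (data units, default 0). A positive floor prevents the scale
#'   estimate from locking onto exactly zero on quantized integer images.
#' @param model_dof Number of parameters of the already-fitted model
#'   (1 for a constant, 2 for a line, 3 for a plane). Used as the
#'   degrees-of-freedom correction in the variance denominator.
#'
#' @return A list of class `msse_config`.
#' @export
#' @examples
#' msse_config(lambda_cutoff = 2.5)
msse_config <- function(lambda_cutoff = 3, k_min = 12L, minimum_residual = 0,
                        model_dof = 1L) {
  stopifnot(is.numeric(lambda_cutoff), length(lambda_cutoff) == 1L,
            lambda_cutoff > 0)
  k_min <- as.integer(k_min)
  model_dof <- as.integer(model_dof)
  if (k_min <= model_dof) {
    stop("`k_min` (", k_min, ") must exceed `model_dof` (", model_dof, ")")
  }
  stopifnot(is.numeric(minimum_residual), minimum_residual >= 0)
  structure(list(lambda_cutoff = lambda_cutoff, k_min = k_min,
                 minimum_residual = minimum_residual, model_dof = model_dof),
            class = "msse_config")
}

#' Robust noise-scale estimation from squared residuals (MSSE)
#'
#' Walks the sorted squared fitting errors and stops at the first point that
#' is statistically inconsistent with the Gaussian scale accumulated so far:
#' starting from `k = k_min`, the running variance is
#' \eqn{\sigma_k^2 = \sum_{j \le k} r_{(j)}^2 / (k - p)} and point `k + 1`
#' is accepted while \eqn{r_{(k+1)}^2 \le \lambda^2 \sigma_k^2}. Points
#' ordered after the stopping index are outliers.
#'
#' @param residuals_sq Numeric vector of nonnegative squared fitting errors,
#'   one per data point.
#' @param config An [msse_config()].
#'
#' @return A list of class `scale_estimate` with elements
#'   `sigma` (estimated inlier noise standard deviation, data units),
#'   `k_inliers` (number of accepted points) and `inlier_flags`
#'   (logical vector in the original point order).
#' @export
#' @examples
#' r <- c(rnorm(70), rnorm(30, mean = 20))
#' est <- msse(r^2)
#' est$sigma
#' est$k_inliers
msse <- function(residuals_sq, config = msse_config()) {
  stopifnot(inherits(config, "msse_config"))
  r2 <- as.numeric(residuals_sq)
  if (anyNA(r2) || any(r2 < 0)) {
    stop("`residuals_sq` must be nonnegative squared residuals without NA")
  }
  n <- length(r2)
  if (n < config$k_min + 1L) {
    stop("MSSE needs at least k_min + 1 = ", config$k_min + 1L,
         " points, got ", n)
  }
  r2 <- pmax(r2, config$minimum_residual^2)
  ord <- order(r2)                       # stable: ties broken by index
  r2s <- r2[ord]
  k_stop <- msse_stop_index(r2s, config)
  p <- config$model_dof
  sigma <- sqrt(sum(r2s[seq_len(k_stop)]) / (k_stop - p))
  flags <- logical(n)
  flags[ord[seq_len(k_stop)]] <- TRUE
  structure(list(sigma = sigma, k_inliers = k_stop, inlier_flags = flags),
            class = "scale_estimate")
}

# Vectorized stopping-rule scan on sorted squared residuals.
msse_stop_index <- function(r2_sorted, config) {
  n <- length(r2_sorted)
  kmin <- config$k_min
  p <- config$model_dof
  lam2 <- config$lambda_cutoff^2
  ks <- kmin:(n - 1L)
  sig2 <- cumsum(r2_sorted)[ks] / (ks - p)
  viol <- r2_sorted[ks + 1L] > lam2 * sig2
  if (any(viol)) ks[which(viol)[1L]] else n
}

#' Weighted MSSE
#'
#' As [msse()], but each point carries a nonnegative weight. Zero-weight
#' points are excluded outright (masking); the remaining points enter the
#' recursion with the weighted mean squared residual
#' \eqn{\sigma_k^2 = (\sum_{j\le k} w_j r_{(j)}^2 / \sum_{j\le k} w_j)
#' \cdot k/(k - p)}, which is invariant to rescaling all weights and reduces
#' exactly to [msse()] on the kept subset for binary 0/1 weights.
#'
#' @inheritParams msse
#' @param weights Nonnegative weights, one per point.
#' @return A `scale_estimate`; `inlier_flags` is `FALSE` for zero-weight
#'   points.
#' @export
msse_weighted <- function(residuals_sq, weights, config = msse_config()) {
  stopifnot(inherits(config, "msse_config"))
  r2 <- as.numeric(residuals_sq)
  w <- as.numeric(weights)
  if (length(w) != length(r2)) {
    stop("`weights` must have one entry per residual")
  }
  if (anyNA(w) || any(w < 0)) stop("weights must be nonnegative")
  if (anyNA(r2) || any(r2 < 0)) {
    stop("`residuals_sq` must be nonnegative squared residuals without NA")
  }
  keep <- which(w > 0)
  if (length(keep) < config$k_min + 1L) {
    stop("weighted MSSE needs at least k_min + 1 = ", config$k_min + 1L,
         " positive-weight points, got ", length(keep))
  }
  r2k <- pmax(r2[keep], config$minimum_residual^2)
  wk <- w[keep]
  ord <- order(r2k)
  r2s <- r2k[ord]
  ws <- wk[ord]
  m <- length(r2s)
  kmin <- config$k_min
  p <- config$model_dof
  lam2 <- config$lambda_cutoff^2
  cw <- cumsum(ws)
  cwr <- cumsum(ws * r2s)
  ks <- kmin:(m - 1L)
  sig2 <- (cwr[ks] / cw[ks]) * ks / (ks - p)
  viol <- r2s[ks + 1L] > lam2 * sig2
  k_stop <- if (any(viol)) ks[which(viol)[1L]] else m
  sigma <- sqrt((cwr[k_stop] / cw[k_stop]) * k_stop / (k_stop - p))
  flags <- logical(length(r2))
  flags[keep[ord[seq_len(k_stop)]]] <- TRUE
  structure(list(sigma = sigma, k_inliers = k_stop, inlier_flags = flags),
            class = "scale_estimate")
}

#' Signal-to-noise ratio as statistical separability
#'
#' SNR of a value against a (robust) background model:
#' `(x - mu_b) / sigma_b`. Sign-preserving, so values below the background
#' get negative SNR (deficient or dead pixels). Note that one published
#' description of this statistic prints it with the background mean in the
#' denominator; the scale-denominator form implemented here is the one
#' consistent with thresholding SNR at a multiple of the noise scale
#' (e.g. the default peak-finding threshold of 6).
#'
#' @param x Value(s) under test (e.g. a pixel intensity).
#' @param mu_b Robust background mean.
#' @param sigma_b Robust background scale; must be strictly positive.
#' @return Unitless SNR, vectorized over the inputs.
#' @export
#' @examples
#' snr(106, 100, 1)   # 6, exactly at the default peak threshold
snr <- function(x, mu_b, sigma_b) {
  if (any(!is.finite(sigma_b)) || any(sigma_b <= 0)) {
    stop("`sigma_b` must be > 0; apply a scale floor (e.g. ",
         "`minimum_residual`) before computing SNR on degenerate scales")
  }
  (x - mu_b) / sigma_b
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat("MSSE scale estimate\n")
  cat("  sigma    :", format(x$sigma, digits = 6), "\n")
  cat("  inliers  :", x$k_inliers, "of", length(x$inlier_flags), "\n")
  invisible(x)
}
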