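test_that("a constant data vector is fitted exactly with zero scale", {
  f <- fit_value(rep(5, 500))
  expect_equal(unname(f$params), 5)
  expect_lt(f$sigma, 1e-12)
  expect_identical(f$k_inliers, 500L)
  f7 <- fit_value(rep(7, 100))
  expect_equal(unname(f7$params), 7)
})

test_that("robust mean survives a 30% far-outlier contamination", {
  d <- gen_1d_dataset(1000, inlier_frac = 0.7, mu = 10, sigma = 2,
                      outlier_low = 40, outlier_high = 100, seed = 8)
  f <- fit_value(d$data)
  expect_lt(abs(f$params[["value"]] - 10), 0.3)
  expect_lt(abs(f$sigma - 2), 0.4)
})

test_that("robust mean beats the plain mean on the asymmetric-outlier demo", {
  d <- gen_1d_dataset(1000, inlier_frac = 0.7, mu = 0, sigma = 0.5,
                      outlier_low = 1.5, outlier_high = 6.5, seed = 21)
  f <- fit_value(d$data)
  expect_lt(abs(f$params[["value"]]), 0.15)
  expect_gt(mean(d$data), 0.3)
})

test_that("fits are bit-reproducible for a fixed rng seed", {
  d <- gen_1d_dataset(500, seed = 12)
  f1 <- fit_value(d$data, flkos_config(rng_seed = 5))
  f2 <- fit_value(d$data, flkos_config(rng_seed = 5))
  expect_identical(f1, f2)
})

test_that("inlier flags are exactly the lambda-sigma threshold rule", {
  d <- gen_1d_dataset(800, inlier_frac = 0.75, mu = 3, sigma = 1,
                      outlier_low = 10, outlier_high = 30, seed = 9)
  msse_cfg <- msse_config()
  f <- fit_value(d$data, msse_cfg = msse_cfg)
  expected <- abs(d$data - f$params[["value"]]) <=
    msse_cfg$lambda_cutoff * f$sigma
  expect_identical(f$inlier_flags, expected)
  expect_identical(f$k_inliers, sum(expected))
})

test_that("downsampled_size >= N reproduces the full fit", {
  d <- gen_1d_dataset(400, seed = 3)
  full <- fit_value(d$data)
  ds <- fit_value(d$data, flkos_config(downsampled_size = 400))
  expect_identical(ds, full)
})

test_that("downsampling fits a subsample but flags every point", {
  d <- gen_1d_dataset(2000, inlier_frac = 0.7, mu = 10, sigma = 2,
                      outlier_low = 40, outlier_high = 100, seed = 10)
  f <- fit_value(d$data, flkos_config(downsampled_size = 500))
  expect_length(f$inlier_flags, 2000L)
  expect_lt(abs(f$params[["value"]] - 10), 0.5)
})

test_that("model_value_init drives a deterministic initial subset", {
  d <- gen_1d_dataset(300, seed = 2)
  f1 <- fit_value(d$data, flkos_config(model_value_init = 0, rng_seed = 1))
  f2 <- fit_value(d$data, flkos_config(model_value_init = 0, rng_seed = 99))
  expect_identical(f1, f2)   # no randomness left when initialized
})

test_that("fit2skewed is no worse on a Gaussian-plus-exponential-tail mixture", {
  bias <- vapply(1:50, function(s) {
    x <- local({
      set.seed(s)
      c(rnorm(600, 5, 1), 5 + rexp(400, rate = 1 / 4))
    })
    sym <- fit_value(x, flkos_config(rng_seed = s))
    skw <- fit_value(x, flkos_config(fit2skewed = TRUE, rng_seed = s))
    c(abs(sym$params[["value"]] - 5), abs(skw$params[["value"]] - 5))
  }, c(0, 0))
  expect_lte(mean(bias[2, ]), mean(bias[1, ]) + 1e-9)
})

test_that("median_of_fits with one repeat reduces to a single fit", {
  d <- gen_1d_dataset(300, seed = 4)
  expect_identical(median_of_fits(d$data, repeats = 1),
                   fit_value(d$data))
})

test_that("median_of_fits is at least as accurate as its worst member", {
  d <- gen_1d_dataset(1000, inlier_frac = 0.7, mu = 10, sigma = 2,
                      outlier_low = 40, outlier_high = 100, seed = 14)
  cfg <- flkos_config(rng_seed = 3)
  med <- median_of_fits(d$data, cfg, repeats = 5)
  singles <- vapply(0:4, function(i) {
    ci <- cfg
    ci$rng_seed <- cfg$rng_seed + i
    fit_value(d$data, ci)$params[["value"]]
  }, 0)
  expect_lte(abs(med$params[["value"]] - 10),
             max(abs(singles - 10)) + 1e-12)
})

test_that("median_of_fits on constant data returns the constant", {
  m <- median_of_fits(rep(4.5, 200), repeats = 3)
  expect_equal(unname(m$params), 4.5)
  expect_lt(m$sigma, 1e-12)
})

test_that("a noiseless line is recovered exactly", {
  x <- seq(-5, 5, length.out = 200)
  f <- fit_line(x, 2 * x + 1)
  expect_equal(f$params[["slope"]], 2, tolerance = 1e-10)
  expect_equal(f$params[["intercept"]], 1, tolerance = 1e-10)
  expect_lt(f$sigma, 1e-8)
})

test_that("planted line is recovered under outliers, near the inlier-only oracle", {
  d <- gen_line_dataset(1000, slope = 2, intercept = 1, sigma = 0.25,
                        outlier_frac = 0.3, seed = 6)
  f <- fit_line(d$x, d$y)
  expect_lt(abs(f$params[["slope"]] - 2), 0.05)
  expect_lt(abs(f$params[["intercept"]] - 1), 0.1)
  ok <- d$truth$is_inlier
  ols <- coef(lm(d$y[ok] ~ d$x[ok]))
  expect_lt(abs(f$params[["slope"]] - ols[2]), 0.05)
})

test_that("the robust line beats full-data least squares under contamination", {
  d <- gen_line_dataset(800, slope = 1.5, intercept = -2, sigma = 0.3,
                        outlier_frac = 0.35, bbox = c(-5, 5, 5, 25),
                        seed = 13)
  f <- fit_line(d$x, d$y)
  ols <- coef(lm(d$y ~ d$x))
  err_rob <- sqrt((f$params[["slope"]] - 1.5)^2 +
                    (f$params[["intercept"]] + 2)^2)
  err_ols <- sqrt((ols[2] - 1.5)^2 + (ols[1] + 2)^2)
  expect_lt(err_rob, err_ols)
})

test_that("line fitting is affine-equivariant in x", {
  d <- gen_line_dataset(600, slope = 2, intercept = 1, seed = 5)
  f0 <- fit_line(d$x, d$y)
  f1 <- fit_line(d$x + 10, d$y)
  expect_equal(f1$params[["slope"]], f0$params[["slope"]], tolerance = 1e-8)
  expect_equal(f1$params[["intercept"]],
               f0$params[["intercept"]] - 10 * f0$params[["slope"]],
               tolerance = 1e-6)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-8)
})

test_that("negating the response negates the fitted line", {
  d <- gen_line_dataset(600, seed = 7)
  f0 <- fit_line(d$x, d$y)
  f1 <- fit_line(d$x, -d$y)
  expect_equal(f1$params[["slope"]], -f0$params[["slope"]],
               tolerance = 1e-8)
  expect_equal(f1$params[["intercept"]], -f0$params[["intercept"]],
               tolerance = 1e-8)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with a rank message", {
  expect_error(fit_line(rep(1, 100), rnorm(100)), "rank-deficient")
  expect_error(fit_plane(1:100, 2 * (1:100) + 3, rnorm(100)),
               "rank-deficient")
})

test_that("a constant field fits a horizontal plane exactly", {
  g <- expand.grid(x = 1:20, y = 1:20)
  f <- fit_plane(g$x, g$y, rep(3, 400))
  expect_equal(unname(f$params), c(0, 0, 3), tolerance = 1e-12)
  expect_lt(f$sigma, 1e-12)
})

test_that("a tilted plane with boosted pixels is recovered and outliers flagged", {
  d <- gen_plane_dataset(grid_shape = c(32, 32), a = 0.1, b = 0.2, c = 50,
                         sigma = 2, outlier_frac = 0.1, boost = 40,
                         seed = 17)
  f <- fit_plane(d$x, d$y, d$z)
  expect_lt(abs(f$params[["a"]] - 0.1), 0.02)
  expect_lt(abs(f$params[["b"]] - 0.2), 0.02)
  expect_lt(abs(f$params[["c"]] - 50), 1.5)
  boosted <- !d$truth$is_inlier
  expect_true(all(!f$inlier_flags[boosted]))
})

test_that("swapping x and y swaps the plane coefficients", {
  d <- gen_plane_dataset(seed = 19)
  f0 <- fit_plane(d$x, d$y, d$z)
  f1 <- fit_plane(d$y, d$x, d$z)
  expect_equal(f1$params[["a"]], f0$params[["b"]], tolerance = 1e-10)
  expect_equal(f1$params[["b"]], f0$params[["a"]], tolerance = 1e-10)
  expect_equal(f1$params[["c"]], f0$params[["c"]], tolerance = 1e-10)
})

test_that("flkos_fit dispatches on the model kind", {
  d <- gen_line_dataset(400, seed = 2)
  f <- flkos_fit(cbind(d$x, d$y), kind = "line")
  expect_identical(f, fit_line(d$x, d$y))
  v <- gen_1d_dataset(200, seed = 2)
  expect_identical(flkos_fit(matrix(v$data), kind = "value"),
                   fit_value(v$data))
})

test_that("the mean estimate is stable across outlier fractions up to 45%", {
  est <- vapply(seq(0, 0.45, by = 0.05), function(fr) {
    d <- gen_1d_dataset(1000, inlier_frac = 1 - fr, mu = 10, sigma = 2,
                        outlier_low = 40, outlier_high = 100, seed = 31)
    fit_value(d$data)$params[["value"]]
  }, 0)
  se <- 2 / sqrt(550)   # inlier standard error at the worst fraction
  expect_lt(max(est) - min(est), 3 * se)
})
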