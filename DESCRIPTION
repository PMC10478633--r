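Package: sxrobust
Title: Robust Gaussian Fitting for Serial Crystallography Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Robust statistical primitives for outlier-contaminated data and
    their serial-crystallography applications. Provides MSSE noise-scale
    estimation from sorted squared residuals, least-kth-order-statistics
    (FLkOS) robust fitting of constants, lines and planes, sliding-window
    robust background estimation for detector images, a robust Bragg-peak
    finder with SNR thresholding and hit classification, and a bad-pixel
    mask maker driven by per-pixel temporal statistics of calibration frame
    stacks. Seeded synthetic-data generators with known ground truth cover
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
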