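Package: yieldtrends
Title: Trend Models and Forecast Evaluation for Crop Yield Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and compares trend models for annual crop yield time
    series: linear, quadratic and cubic regression, linear-plus-plateau
    (segmented) regression with explicit convergence diagnostics,
    non-seasonal Holt-Winters exponential smoothing with and without a
    trend term, and two dynamic linear models (random-walk local level and
    local linear trend) built on an internal Kalman filter and smoother
    with maximum-likelihood variance estimation. Provides rolling-origin
    k-step-ahead prediction-error evaluation (RMSEP) over panels of
    geographical units, dynamic estimation of yearly yield-increase rates
    with uncertainty bands, and a seeded synthetic-panel generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
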