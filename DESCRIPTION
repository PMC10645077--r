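Package: carbondyn
Title: Radiocarbon Summed Probability Distributions and
    Competition-Cooperation Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Palaeodemographic time-series analysis from radiocarbon date
    lists: per-date calibration against an atmospheric calibration curve,
    site-wise binning, summed probability distributions (SPDs) as a
    relative population proxy, proxy covariate preparation (period-score
    interpolation, min-max merging, exact cubic smoothing splines), fitting
    of Ricker-type competition-cooperation growth-rate models with
    exogenous covariates by least squares, AICc multimodel inference with
    Akaike weights and predictor importances, and validation by total
    trajectory simulation scored with the coefficient of prediction. A
    synthetic-data module generates known-truth date collections and
    covariate series so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
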