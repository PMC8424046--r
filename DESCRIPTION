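Package: chromcast
Title: Predictive Chromatography from Greenhouse Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Chromcast", "Maintainers", email = "maintainers@chromcast.dev",
           role = c("aut", "cre"))
Description: Predicts the LC-UV chromatogram of plant leaf extracts from
    multichannel greenhouse sensor time series. Sensor logs (soil pH, soil
    moisture, temperature, relative humidity, light) are regularized to a
    per-minute grid, gap-filled by stochastic regression imputation,
    normalized with trailing-window technical indicators, and encoded as
    128 x 128 Gramian angular field images. A small convolutional network
    maps the image stack to the log relative-concentration profile of the
    extract. Chromatograms are baseline-corrected with a sparsity-assisted
    (BEADS-type) estimator and area-normalized before training. Predictions
    are scored with lag-tolerant cross-correlation, R-squared, and a
    peak-matching Matthews correlation coefficient MCC(n) whose tolerance
    multiplier n is selected by a signal-to-noise optimizer. A synthetic
    data generator with known ground truth makes the full pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
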