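Package: gruae
Title: GRU Autoencoder Health Monitoring for Vital-Sign Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised health monitoring of hourly multivariate vital-sign
    streams (body temperature and heart rate) by reconstruction error. A
    three-layer gated recurrent unit autoencoder (GRU-AE) with a fully
    connected sigmoid head is trained on healthy data only and scores each
    incoming hour by its half-squared reconstruction error; losses exceeding
    a quantile-calibrated threshold raise health alarms. Includes a
    memoryless feedforward autoencoder baseline, a synthetic circadian
    vital-sign cohort simulator with injected fever episodes, chronological
    train/test splitting and min-max normalization, a streaming monitor, and
    an evaluation suite (MAE/RMSE, confusion rates under the healthy-as-
    positive convention, ROC and rank-statistic AUC). The batched
    forward/backward pass is implemented in C++ via RcppArmadillo, with a
    pure-R double-precision reference implementation used for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
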