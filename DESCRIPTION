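Package: sigmaqc
Title: Six Sigma-Stratified Dynamic Quality Control for Hematology Analytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for patient-based real-time quality control (PBRTQC) of
    hematology analytes. Implements sigma-metric performance assessment with a
    patient-CV matrix correction factor, sigma-stratified QC plan assignment,
    an adaptive-window moving-average monitor of patient result streams, a
    Westgard multirule engine for control materials, a small LSTM forecaster
    that raises a red alert when the predicted mean deviation of upcoming
    samples exceeds a fraction of the total allowable error, a three-tier
    orchestrator (prediction, monitoring, rule verification) with event
    classification and lead-time summaries, diagnostic-accuracy and agreement
    evaluation, and a seeded synthetic patient/QC stream simulator with
    injectable step shifts, drifts, outliers and pre-analytical flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
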