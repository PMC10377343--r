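Package: ppghr
Title: Heart-Rate Reconstruction from Motion-Corrupted Wrist PPG
Version: 0.1.0
Authors@R:
    person("ppghr", "developers", email = "ppghr@example.org", role = c("aut", "cre"))
Description: Two-stage machine-learning pipeline that reconstructs a wearer's
    heart-rate time series from wrist photoplethysmography (PPG) corrupted by
    arm and finger motion. An activity classifier routes each 6-second window
    either to FFT-based heart-rate extraction from the band-passed PPG (rest)
    or to one of two trained regressors (Gaussian-process regression and
    bagged regression trees) that estimate heart rate from wristband features
    dominated by skin temperature. Includes a synthetic wearable-session
    simulator built on a Beer-Lambert motion-artifact model, Pan-Tompkins QRS
    detection for ECG-derived ground truth, NCA and RReliefF feature
    weighting, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
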