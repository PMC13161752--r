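Package: anesEEG
Title: Quantitative EEG Spectral Signatures of Anesthetic Maintenance Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentiates propofol- from sevoflurane-maintained general
    anesthesia from frontal electroencephalography (EEG). Implements epoch-level
    Welch power spectra, periodic band-power/edge/entropy features, a
    specparam-style decomposition of each spectrum into an aperiodic 1/f
    background (offset, exponent) plus Gaussian oscillatory peaks, two-stage
    power-threshold artifact rejection, subject-independent grouped
    cross-validated random-forest classification with exact TreeSHAP feature
    attribution, and Welch's t group statistics with Spearman correlation
    clustering. Ships a calibrated synthetic frontal-EEG cohort generator with
    drug-specific spectral presets and ground truth, so the full pipeline is
    testable end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
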