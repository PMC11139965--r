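Package: emgoa
Title: EMG Gait Analysis and Interpretable Severity Estimation for Knee Osteoarthritis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline from raw multi-channel surface
    electromyography (EMG) recorded during gait to patient-reported knee
    osteoarthritis severity estimates. Implements band-pass and 60 Hz notch
    filtering, signal-to-noise-ratio epoch gating, full-wave rectification,
    linear-envelope extraction, gait-cycle time normalization to 101 points,
    Rudolph co-contraction indices and fiducial waveform features, WOMAC and
    VAS scoring with midpoint-rule severity categorization, random-forest
    regression of the patient-reported outcomes with univariate feature
    selection and cross-validated depth tuning, and exact interventional
    Shapley-value attribution for the fitted tree ensembles. Ships a
    synthetic cohort generator so every stage is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
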