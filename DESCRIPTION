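Package: tbsa
Title: Tracheal Breathing Sound Analysis for Sleep-Apnea Severity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of wakeful tracheal breathing sounds for obstructive
    sleep apnea (OSA) severity assessment. Provides a severity-dependent
    synthetic cohort generator (breath-sound waveforms plus anthropometric
    records), breath-phase segmentation and band-pass preprocessing,
    multi-domain acoustic feature extraction (Welch spectral descriptors,
    bispectral gap regions detected via bootstrap confidence intervals,
    bounding-box morphology and gray-level co-occurrence texture, fractal and
    recurrence metrics, wavelet/MFCC/constant-Q statistics), three-stage
    feature selection (univariate AUC filter, tree-SHAP ranking, recursive
    feature elimination), and covariate-balanced stratified cross-validation
    of bagged one-vs-one tree ensembles with feature-stability and
    anthropometric-correlation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
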