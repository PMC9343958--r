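Package: sweetEEG
Title: Taste-Stimulus EEG Classification with a Multi-Branch 1D CNN
Version: 0.1.0
Authors@R:
    person("Gustav", "Analyst", email = "sweeteeg@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-channel gustatory-cortex EEG
    recorded while subjects taste water or equi-sweet sucrose, aspartame
    and sucralose solutions. Provides a synthetic EEG generator (1/f
    background plus class-specific band-limited oscillations under an
    onset envelope), artifact screening, zero-phase Butterworth bandpass
    filtering, fractional-stride sliding-window segmentation, per-window
    normalization, segment- or group-level train/test splitting, a
    three-branch one-dimensional convolutional network trained with Adam
    on categorical cross-entropy, an FFT band-power baseline classifier,
    one-vs-rest confusion-matrix metrics with macro averages, grand-average
    signal traces, visual-analog-scale participant screening, and a
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
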