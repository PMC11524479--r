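Package: wingbeatr
Title: Noise-Robust Classification of Mosquito Wingbeat Sounds from Raw Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying mosquito species and sex from raw wingbeat
    audio under environmental background noise. Provides WAV ingestion and
    standardization to 8 kHz / 16-bit, fixed-length 300-ms epoch segmentation,
    an additive noise-overlay simulator with adjustable wingbeat gain, a
    stochastic training-time augmentation pipeline (environmental-noise
    overlay, wingbeat volume variation, Gaussian noise, time shifting,
    amplitude variation), a raw-waveform one-dimensional convolutional
    network trained with weighted cross-entropy and Adam, a stratified
    chronological k-fold evaluation protocol with per-class and
    macro-averaged metrics, one-sided Mann-Whitney comparison of runs,
    dual-microphone noise subtraction, and a synthetic wingbeat and noise
    generator so the whole pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
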