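Package: icafeat
Title: Independent Component Analysis and Entropy Feature Extraction for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature extraction and two-class emotion classification for
    multichannel EEG. Implements fixed-point (FastICA-style) independent
    component analysis with PCA whitening and a logcosh negentropy contrast,
    non-overlapping windowed FFT rhythm-band energies, sample entropy,
    approximate entropy and composite multiscale entropy, a synthetic-data
    generator for blind-source-separation benchmarks and two-class emotion
    EEG, and a stratified cross-validated linear-SVM evaluation harness that
    compares ICA-component features against raw-channel features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
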