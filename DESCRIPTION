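Package: bleatr
Title: Classification and Explanation of Goat Vocalizations from Log-Mel Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A toolkit for context classification of farm-animal (goat)
    vocalizations and for explaining the resulting predictions. Provides a
    log-Mel spectrogram frontend (22050 Hz, 128 mel bands), phase-vocoder
    time-stretch and pitch-shift augmentation, a VGG-style convolutional
    network trained with Adam under stratified k-fold cross-validation,
    conditional (concept) relevance propagation with sample-wise channel
    rankings and class-wise average heatmaps, an interactive four-question
    explanation interface with spectrogram-mask sonification and
    embedding-space retrieval, and a seeded synthetic call generator so the
    whole pipeline is testable without external audio corpora.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
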