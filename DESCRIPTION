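Package: semgmeta
Title: Fast-Adaptive Surface-EMG Gesture Recognition with Attention
    Convolution Networks and Meta-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding hand gestures from multichannel surface
    electromyography (sEMG). Implements the full pipeline: band-stop
    preprocessing of high-density electrode-grid recordings, short-time
    Fourier transform spectrogram features, a compact convolutional
    network with channel and spatial attention (CSAC-Net) written from
    scratch with analytic gradients, N-way K-shot episodic task
    construction, and model-agnostic meta-learning (MAML) for rapid
    adaptation to new subjects. Ships a synthetic high-density sEMG
    generator with subject-specific gain, electrode shift and powerline
    interference, so every stage is exercisable without external data,
    plus a loader for MAT-format electrode-grid datasets.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
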