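Package: msdsanet
Title: Multimodal EEG and Peripheral-Signal Emotion Recognition with
    Multi-Scale Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements MSDSANet, a multimodal emotion-recognition model that
    couples a dual-stream EEG feature extractor (a raw time-series stream and a
    multi-scale attention residual block operating on a 10-20 electrode grid)
    with a dual-scale convolutional-LSTM branch for peripheral signals (EOG or
    ECG), fused through convolutional block attention (CBAM) and efficient
    channel attention (ECA). Includes a reproducible synthetic generator for
    DEAP-like and DREAMER-like recordings, sliding-window preprocessing with
    baseline correction and label binarization, SNR-controlled noise injection,
    a from-scratch reverse-mode automatic-differentiation engine used to train
    the network by mini-batch SGD, stratified cross-validation with accuracy,
    Cohen's kappa, F1, sensitivity and specificity reporting, ablation
    configurations, and a t-SNE feature-embedding visualizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
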