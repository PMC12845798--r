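Package: hrfusion
Title: Multimodal Heart-Rate Regression from Ballistocardiogram and
    Photoplethysmogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contactless heart-rate estimation from bed-sensor
    ballistocardiogram (BCG) and photoplethysmogram (PPG) recordings. The
    package provides a synthetic cardiomechanical signal simulator with
    known beat times, a preprocessing pipeline (zero-phase band-pass
    filtering, polyphase resampling to 100 Hz, ECG R-peak detection,
    sliding-window segmentation with RR-derived labels, physiological
    outlier exclusion and per-window z-scoring), a dual-branch temporal
    fusion network combining multi-scale causal convolutions, temporal
    convolutional blocks, bidirectional LSTMs, multi-head self-attention
    and cross-modal attention fusion, a training loop with Huber loss,
    Nadam optimisation, plateau learning-rate decay, early stopping and
    cross-validation, and Bland-Altman agreement analysis of the
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
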