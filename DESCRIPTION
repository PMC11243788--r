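Package: semgknee
Title: Knee-Angle Estimation from Surface EMG with an Attention-Based
    Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the knee flexion angle during walking from multichannel
    surface electromyography (sEMG). Implements the full pipeline: multi-stage
    EMG conditioning (Hampel outlier removal, zero-phase band-pass filtering,
    rectification, peak and RMS envelope detection, low-pass smoothing),
    gait-cycle segmentation and time normalization, an encoder-decoder gated
    recurrent unit (GRU) regressor with Bahdanau attention trained by
    backpropagation through time with ADAM, evaluation metrics (RMSE, Pearson
    correlation, SNR, NRMSE, convergence rate), experiment protocols
    (attention-vs-baseline comparison, channel-ablation sensitivity, transfer
    learning with stride-level personalization, sequential and multi-visit
    adaptation), and a physiologically structured synthetic gait sEMG
    generator with healthy and cerebral-palsy walking presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
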