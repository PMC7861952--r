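Package: semgfuse
Title: Surface-EMG Gesture Classification with Virtual-Sample Augmentation and Per-Class Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multistage pipeline for surface electromyography (sEMG) gesture
    recognition on small recorded datasets: short-time Fourier spectrogram
    representation of multichannel signals, class-conditional Gaussian
    virtual-sample generation to enlarge scarce training sets, a multiway
    (tensor) view of the time-frequency features with coordinate-transform
    utilities, stacked sparse-autoencoder feature learning, and a bank of
    extreme learning machine, support vector machine and softmax classifiers
    fused by per-class best-local-classifier selection. Includes a synthetic
    sEMG simulator, threefold cross-validation with per-subject accuracy
    averaging, and a reproducible seeded orchestrator.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    nnet,
    MASS,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
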