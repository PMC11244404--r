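Package: hypnoseeg
Title: EEG Pipeline for Identifying Road Hypnosis in Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation, preprocessing and classification of frontal EEG for
    driver-state research, built around the road-hypnosis (RH) versus normal
    driving (ND) two-class problem. Provides a labeled synthetic EEG generator
    with oscillatory band sources and ocular/cardiac artifacts, bilateral
    mastoid re-referencing, linear-phase FIR filtering, a from-scratch FastICA
    with automated artifact-component scoring, event-locked epoch extraction,
    periodogram power spectral density band features, compact convolutional
    (EEGNet-style) and recurrent (RNN/LSTM) classifiers trained with a
    60/20/20 hold-out protocol, and confusion-matrix metrics (accuracy,
    sensitivity, specificity, geometric mean).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
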