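Package: smokescreen
Title: Smoking Activity Recognition from Wearable sEMG and IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, featurization, classification and evaluation pipeline
    for recognizing cigarette-smoking hand gestures from a forearm-worn sensor
    band combining eight surface-electromyography (sEMG) channels with a
    three-axis accelerometer and gyroscope, all sampled at 200 Hz. Provides a
    synthetic cohort generator emulating a scripted protocol of daily-living
    activities with periodic puff gestures, sliding-window segmentation with
    overlap-based labeling, multi-channel spectrogram imaging via the
    short-time Fourier transform, a convolutional-recurrent (CNN-LSTM) window
    classifier implemented on base linear algebra, sequential forward selection
    of sEMG channels, and leave-one-subject-out evaluation with accumulated
    confusion matrices, micro/macro metrics and exact McNemar paired tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
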