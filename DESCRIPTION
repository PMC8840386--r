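Package: sardar
Title: Wearable-Based Behavior Recognition for Search and Rescue Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising the behaviour of search-and-rescue (SaR) dogs
    from a back-mounted wearable carrying a 100 Hz inertial measurement unit
    (3-axial accelerometer + 3-axial gyroscope) and a microphone. Implements the
    full desk-side pipeline: orientation-independent magnitude extraction and
    training-set z-normalisation of IMU streams, 2-s/50%-overlap windowing, a
    late-sensor-fusion convolutional network for stand-vs-search activity
    recognition, a log-mel spectrogram front end and a lightweight convolutional
    network for bark detection, classic feature-based baselines (logistic
    regression, k-NN, decision tree, random forest), leave-one-session-out
    cross-validation with repeated-run averaging, and an alert rule that raises
    a victim-found event when the dog is standing and barking simultaneously.
    A seeded synthetic-data generator emulates labelled SaR sessions so the
    whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    class,
    rpart,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
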