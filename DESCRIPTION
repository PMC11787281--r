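Package: somnimu
Title: Sleep Apnea Respiratory-Event Screening from Wrist-Worn IMU Recordings
Version: 0.1.0
Authors@R:
    person("Somnimu", "Developers", email = "somnimu@example.org", role = c("aut", "cre"))
Description: Detects sleep-apnea respiratory events from 60 Hz wrist-worn
    inertial measurement unit (triaxial accelerometer plus gyroscope)
    recordings. Band-limited FIR decomposition separates mechanocardiographic
    (4-11 Hz), respiratory wrist-motion (0.13-0.70 Hz) and gross body-movement
    (2.0-3.0 Hz) components; a frequency stability index quantifies spectral
    concentration around the dominant peak; fast/slow 95th-percentile
    envelopes of the respiratory scalar localise transient amplitude dips and
    their geometric features. Per 30-second epoch, fifteen features feed
    SMOTE-balanced classifiers (logistic regression, random forest, gradient
    boosting, k-nearest neighbours, multilayer perceptron) to flag
    event-containing epochs, and the hourly rate of flagged epochs estimates
    the apnea-hypopnea index per subject. A synthetic sleep-IMU generator
    with ground-truth annotations makes the whole pipeline testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
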