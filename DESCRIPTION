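Package: normwear
Title: Deep Normative Modeling for Novelty Detection in Wearable Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic novelty detection for multi-channel accelerometer
    (IMU) time series. Models the distribution of normal movement windows with
    a convolutional denoising autoencoder, quantifies per-feature deviations of
    test windows as normative probability maps using Monte-Carlo-dropout
    predictive uncertainty, and converts block-maxima summaries of those
    deviations into abnormality probabilities via a generalized extreme value
    distribution. Includes reconstruction-error and one-class SVM novelty
    baselines, a leave-one-subject-out evaluation harness with AUC/AUPR
    metrics, and a seeded synthetic gait/tremor signal generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
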