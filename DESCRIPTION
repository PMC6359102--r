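Package: tsvr
Title: Transductive Support Vector Regression for Wearable Stress Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Continuous stress recognition from peripheral physiological
    signals (blood volume pulse and galvanic skin response) recorded by
    wrist-worn sensors. Extracts non-linear time-frequency features from
    short sliding windows (wavelet-packet band splitting, inter-beat
    interval statistics, third-order-cumulant spectral features,
    skin-conductance-response peak statistics) and predicts a continuous
    stress label per test instance with a transductive epsilon-SVR: a
    neighborhood of training examples is selected in kernel feature space,
    penalized by robust label dispersion (median/MAD), and an
    instance-weighted epsilon-SVR is fitted locally. Provides within-subject
    (ST-SVR) and pooled-subject (T-SVR) training modes, inductive epsilon-SVR
    and linear-regression baselines, an evaluation harness (MAE, three-level
    stress F1), and synthetic-signal generators for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
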