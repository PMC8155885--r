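Package: mseabc
Title: Multiscale Entropy Features and Artificial Bee Colony Feature
    Selection for EEG Event Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting implicit-learning-related events in
    epoched EEG. Converts multichannel EEG into multiscale sample entropy
    (MSE) profiles per frontal channel and frequency band, labels trials
    fast or slow from behavioral response times via the Triple Response
    Time (TRT) rule, selects informative (channel, band) features with a
    binary Artificial Bee Colony (ABC) optimizer whose fitness is
    cross-validated classifier accuracy, and compares ABC against
    no-selection baselines with confusion-matrix metrics, ROC curves and
    t-tests. Includes a seeded synthetic-data generator so the whole
    pipeline is testable without any recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    rpart,
    randomForest,
    e1071,
    class,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
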