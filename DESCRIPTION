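Package: zratio
Title: Ratiometric Finger-Pair Bioimpedance Features for Biometric
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ratiometric analysis of multi-frequency finger-pair
    bioimpedance spectra as a biometric trait. Provides a closed-form
    equivalent-circuit simulator of finger-pair impedance (four RC Z-blocks:
    electrode/epidermis interfaces, dermis, sweat ducts), a synthetic cohort
    generator with session-level common-mode drift and inverse temperature
    dependence, the ratiometric feature transform with exact derangement-based
    combination selection, and an open-set identification benchmark
    (leave-one-session-out cross-validation, FAR/FRR threshold sweep, EER and
    AUC) over linear/quadratic SVM, 1-NN and bagged-tree classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
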