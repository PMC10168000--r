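Package: idsleuth
Title: Machine-Learning Classification of Biological Database Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies bare biological database identifier strings (accessions)
    into their source database. Identifiers are encoded as fixed-width integer
    vectors of positional character codes, class imbalance is corrected by
    stratified splitting plus SMOTE oversampling, redundant padded positions are
    removed by correlation and Gini-importance filters, and four classifiers
    (CART, random forest, XGBoost and a two-hidden-layer neural network) are
    tuned with hyperband and unified by majority voting with a
    misclassification-aware scoring fallback. Ships a registry of 39 synthetic
    identifier patterns emulating common databases, a seeded corpus generator,
    per-class evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    rpart,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
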