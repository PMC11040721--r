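Package: fingertox
Title: Bioassay Activity Prediction from Probabilistic Molecular Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting bioassay activity of unidentified chemicals
    from molecular fingerprint features. Implements Monte Carlo sampling for
    consuming probabilistic (posterior) fingerprints with classifiers trained
    on binary fingerprints, a missing-label-masked multi-label cross-entropy
    network, anticlustering-based train/test partitioning and cross-validation
    folds, imbalance resampling (down/up/SMOTE), near-zero-variance and
    correlation feature filters, and evaluation by false-positive rate at
    fixed recall. Ships a synthetic data generator with planted toxicophores
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB,
    caret,
    pROC
Config/testthat/edition: 3
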