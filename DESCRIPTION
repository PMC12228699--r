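Package: tastekit
Title: Molecular Taste Prediction from SMILES with Consensus Confidence and
    Atom-Level Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for predicting the taste of small molecules (sweet,
    bitter, sour, umami, or undefined) from their SMILES representation.
    Provides dataset curation (validity, fragment, charge and molecular
    weight filters with canonical-SMILES deduplication and report),
    leakage-safe train/test splitting, Morgan fingerprint and topological
    descriptor featurization, pluggable multi-class classifiers
    (gradient-boosted trees, random forest, balanced random forest, and a
    small token-level transformer), a test-time-augmentation consensus
    confidence metric with abstention, integrated-gradients atom
    attribution, an imbalanced-class evaluation suite (macro and weighted
    averages, one-vs-rest AUROC, binary reduction, multi-label analysis),
    seeded synthetic tastant data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
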