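Package: nifstack
Title: Stacking Ensembles for Predicting Nitrogenase Activity from Genomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts microbial nitrogenase activity (acetylene reduction,
    nmol C2H4/mg protein/hour) from genomic information. Encodes nifH/nifD/nifK
    proteins and nif-operon coding sequences into nine feature groups (conjoint
    triad, dipeptide composition, pseudo-amino-acid composition, relative
    synonymous codon usage, codon-usage distance, expression indices CAI/E/Fop,
    gene distance, gene copy numbers, and protein language-model embeddings),
    selects feature groups by greedy incremental search under cross-validation,
    selects base learners by incremental mutual information, and fits two-layer
    stacking ensembles for classification (active/inactive at a 50 nmol
    threshold) and regression (log-transformed activity). Includes a
    deterministic synthetic-data generator with planted signal so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
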