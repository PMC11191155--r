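Package: consensusMarkers
Title: Consensus Multi-Algorithm Feature Selection for Robust Composite
    Biomarker Discovery in Imbalanced Transcriptomics Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A batch-aware machine-learning pipeline for in-silico discovery
    of composite transcriptomic biomarkers from multi-cohort bulk RNA-seq
    counts. Provides TMM normalisation and log-CPM transformation, train-set
    derived gene filters (low expression, low fold change, cross-batch
    inconsistency), ASCA-style removal of systematic batch variance,
    ADASYN oversampling for class imbalance, and a consensus variable
    selection engine that aggregates LASSO, Boruta-style shadow-feature
    search and varSelRF-style backward elimination across cross-validation
    folds and resampled models. Candidate gene sets feed imbalance-aware
    random-forest models evaluated with a twelve-metric protocol (per-class
    and macro precision/recall/F1, ROC-AUC, PR-AUC, MCC) over repeated
    splits, cross-dataset validation and recalibration. A negative-binomial
    multi-batch simulator with planted signature genes makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    glmnet,
    ranger,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
biocViews: Transcriptomics, FeatureExtraction, Classification,
    BatchEffect, Normalization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
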