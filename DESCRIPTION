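Package: cfRNAprog
Title: Cell-Free RNA Profiling of Pregnancy Progression and Pre-Eclampsia Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for plasma cell-free RNA (cfRNA) profiles in
    pregnancy: multi-cohort negative-binomial count simulation with known
    ground truth, sequencing-depth and orthogonal cohort-effect correction
    with a strict no-leakage train/apply contract, an L1-penalised
    gestational-age clock with one-standard-error model selection and ANOVA
    variance decomposition, gene-set transcriptome-partitioning trend and
    exact-null monotonicity analysis over longitudinal draws, and a
    pre-eclampsia risk classifier with fold-internal Spearman feature
    screening, bootstrap confidence intervals and positive-predictive-value
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    survival,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Regression, Classification,
    BatchEffect, Survival
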