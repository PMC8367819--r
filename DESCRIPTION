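Package: clinbench
Title: Benchmarking Clinical Tabular Classifiers with Multi-Graph
    Geometric Matrix Completion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking machine-learning classifiers on
    mixed-type clinical registry tables. Implements a reproducible
    pipeline of winsorization, z-transformation, one-hot encoding and
    mean imputation with a missingness drop rule; stratified k-fold
    cross-validation with nested random-search hyperparameter tuning;
    a registry of eleven classifiers including a from-scratch
    transductive multi-graph geometric matrix completion (MGMC) model
    built on Chebyshev spectral graph filters; feature-importance
    extraction (coefficients, Gini impurity, Integrated Gradients,
    permutation) aggregated across classifiers by relative aggregation
    of feature importance (RAFI); per-feature hypothesis-test routing;
    a seeded synthetic-cohort generator; and a multi-panel report with
    metrics, confusion matrices and a 2D embedding of the input space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    e1071,
    kernlab,
    rpart,
    ranger,
    glmnet,
    uwot,
    jsonlite,
    yaml,
    ggplot2,
    patchwork,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
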