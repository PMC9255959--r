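Package: ConfoundCV
Title: Confound-Aware Cross-Validated Prediction for Multi-Site Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Machine-learning analysis of multi-site cohort feature tables in
    the presence of categorical confounds such as sex and recruitment site.
    Implements three confound-correction techniques (linear confound
    regression, counterbalancing by undersampling and by oversampling), a
    five-way same-analysis diagnostic battery that probes every input-output
    pathway between features, confounds and labels, a two-stage nested
    cross-validation / holdout evaluation with train-label permutation
    significance testing, leave-one-site-out generalization, and
    permutation-Shapley feature attribution with a stability rule for
    selecting reliably informative features. A multi-site cohort simulator
    with known generative truth (confound pathways and label signal) makes
    every stage testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
LinkingTo: Rcpp, RcppArmadillo
biocViews: Classification, StatisticalMethod, BatchEffect, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
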