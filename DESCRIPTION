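Package: piramir
Title: miRNA-Based Modelling of Disability Progression in Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling Progression Independent of Relapse Activity
    (PIRA) and 24-month EDSS change from baseline PBMC miRNA expression in
    relapsing-remitting multiple sclerosis. Implements median normalization
    and expression filtering for miRNA microarray intensity matrices,
    PIRA/RAW labelling from confirmed-disability-worsening and relapse
    events, dual Pearson-correlation candidate screening with Shapiro-Wilk
    diagnostics, exhaustive significance-constrained search over logistic
    and linear models with pairwise interaction terms, ROC/Youden
    classification, and bootstrap and randomization robustness tests for
    the AUC. A synthetic-cohort simulator reproduces the statistical
    structure of the study design (cohort composition, EDSS trajectory
    moments, and exact requested feature-outcome correlations) so the full
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
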