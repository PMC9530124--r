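Package: treemort
Title: Explainable Tree-Ensemble Modelling of All-Cause Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and explaining gradient-boosted-tree models of
    all-cause mortality from tabular cohort data. Provides a synthetic cohort
    generator with planted non-linear risk effects, feature redundancy and
    interactions; cross-validated gradient-boosted-tree classifiers with a
    regularized logistic baseline and bootstrap AUROC evaluation; exact
    interventional Shapley attributions with pairwise interaction
    decomposition and a brute-force oracle; a supervised-distance redundancy
    metric with complete-linkage feature clustering and redundancy-aware
    recursive feature selection; relative-risk partial-dependence audits of
    laboratory reference intervals; and tiered, cost-aware mortality risk
    scores with individualized explanations and temporal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
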