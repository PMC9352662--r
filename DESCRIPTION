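Package: perisk
Title: Extinction-Risk Probabilities for Data Deficient Species from
    Spatially Summarized Stressors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, fully synthetic-data-driven pipeline for
    predicting each species' probability of being threatened by extinction
    (PE score) from stressor layers summarized over range maps and
    occurrence cells on a global 0.5-degree grid. Includes a seeded
    synthetic world generator with a known logistic threat-generating
    process, zonal feature extraction, binary Red List reclassification
    with stratified splitting and minority oversampling, shadow-feature
    (Boruta-style) relevance filtering, a stacked super-learner with a
    non-negative L1-regularized logistic meta-learner, a full evaluation
    suite (confusion-matrix metrics, AUC, AUC_PR, Gini, permutation
    importance), and spatial conservation-priority aggregation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    geosphere,
    glmnet,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
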