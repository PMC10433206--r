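Package: zipforest
Title: Iterative Random Forests for ZIP-Code-Level Case-Control Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An explainable-AI pipeline for predicting rare binary outcomes
    (case/control status) from areal covariates attached to patients by ZIP
    code. Implements iterative Random Forests (iRF): variance-reduction
    regression trees on 0/1 labels with per-iteration feature reweighting,
    correlation pruning of near-duplicate features, group-shuffled
    cross-validation scored by the area under the precision-recall curve,
    split-based estimation of each feature's risk or protective direction,
    reduced-model selection (top-ranked features plus forced covariates), and
    all-against-all iRF-LOOP feature network inference. Ships a synthetic
    cohort generator with planted causal signals, correlated feature groups,
    and an age-structured prevalence regime so every stage is testable without
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    digest
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    randomForest,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
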