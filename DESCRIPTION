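Package: liquidcascade
Title: Multi-Level Cancer Classification for Liquid-Biopsy Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seven-level binary classification cascade for plasma
    liquid-biopsy cohorts (39 protein biomarkers, demographics and a
    cfDNA mutation omega score). Implements majority-vote feature
    selection over six scorers (information value with monotonic
    binning, chi-square, random-forest and extra-trees importances,
    recursive feature elimination and L1-penalized linear selection),
    per-level soft-voting ensembles of gradient-boosted trees, random
    forests, extremely randomized trees and quadratic discriminant
    analysis, confusion-matrix evaluation with macro averaging across
    levels, Friedman average-rank and Wilcoxon signed-rank method
    comparison, an assay cost model, and a synthetic cohort generator
    with planted informative markers so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
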