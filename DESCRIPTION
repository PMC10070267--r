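Package: tepseq
Title: Tumour-Educated Platelet RNA-Seq Classification and Confounding Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a liquid-biopsy classification pipeline for
    tumour-educated platelet (TEP) RNA-seq count data: post-alignment quality
    control, subset-aware TMM normalisation, dual-threshold RUV factor
    correction, particle-swarm-optimised SVM and elastic-net classifiers,
    ROC evaluation with DeLong confidence intervals, and a suite of
    batch-confounding diagnostics (per-gene variance partitioning,
    negative-binomial differential expression, ComBat comparison,
    over-representation tests and contamination scores). Ships a synthetic
    count-data generator that emulates a confounded multicentre case-control
    design, so the entire pipeline is testable end to end without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    e1071,
    lme4,
    edgeR,
    sva,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
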