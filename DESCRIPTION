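Package: gempert
Title: Adversarial Perturbation of Gene Expression States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns per-gene perturbations that shift a bulk RNA-seq
    expression sample from a source class (for example a tumor subtype)
    to a target class (for example healthy tissue) using a least-squares
    generative adversarial network trained against a frozen multi-class
    expression classifier. The learned perturbation vector for a single
    unreplicated sample is then thresholded into per-sample lists of
    up- and down-regulated genes, an "n = 1" surrogate for cohort
    differential-expression analysis. Includes the full normalization
    chain for FPKM-like expression matrices (log2, quantile, gene-set
    subsetting, per-gene min-max scaling), a synthetic-data generator
    for multi-class and paired tumor/normal designs, and downstream
    comparison utilities (per-sample gene lists, between-patient overlap
    ratios, and overlap with external differential-expression tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
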