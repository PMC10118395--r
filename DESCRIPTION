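Package: stepblup
Title: Single-Step SNP BLUP Genomic Evaluation for Beef Carcass Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait single-step genomic evaluation for beef cattle
    carcass traits (carcass weight, eye muscle area, backfat thickness,
    marbling score). Implements pedigree relationship algebra with
    inbreeding and unknown-parent (phantom) groups, single-step SNP BLUP
    with residual polygenic effects, the equivalent single-step GBLUP
    formulation, conventional pedigree BLUP, forward validation by the
    linear-regression (LR) method, standardized SNP-effect scans, genetic
    trends, and a gene-dropping simulator of a multi-generation breeding
    population for end-to-end testing of the whole pipeline.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
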