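Package: fpcatest
Title: FPCA-Based Significance Testing for Time-Course Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes in time-course
    expression experiments without replicates. Gene trajectories are
    represented with data-driven eigenfunctions obtained by functional
    principal component analysis (FPCA) of a covariance surface pooled
    across all genes, so that individual-gene inference borrows strength
    from the whole array. Non-flat profiles (one group) and between-group
    profile differences (multiple groups) are tested with a
    variance-stabilized F-statistic whose null distribution is generated
    by permutation, with genewise or pooled permutation p-values and
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    data generator and an evaluation harness for power and type-I-error
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
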