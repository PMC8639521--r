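Package: gpcv
Title: Paired Cross Validation for Comparing Genomic Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing genomic prediction models by r-replicated
    k-fold paired cross validation. Builds the standard genomic relationship
    matrices and epistatic kernels (VanRaden G, Hadamard-square H, categorical
    marker-match kernels, Gaussian RKHS kernels) from biallelic dosage panels,
    fits Bayesian-alphabet marker regressions (ridge regression BLUP, BayesA,
    BayesB, BayesC) by Gibbs sampling and (multi-)kernel mixed models by REML,
    and evaluates them on shared fold partitions so that per-fold accuracy
    differences cancel the variability common to all models. Accuracy
    differences can be rescaled to expected genetic gain under truncation
    selection, and judged against a user-supplied equivalence margin with
    statistical-difference, equivalence (TOST), non-inferiority and
    superiority tests, summarised as equivalence letters (maximal cliques)
    and non-inferiority/superiority rankings (topological layering). Includes
    a synthetic-data module for marker panels and additive plus pairwise
    epistatic trait architectures, paired-vs-unpaired power curves, tidy
    accessors and plots, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
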