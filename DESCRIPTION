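Package: maternalfx
Title: Maternal Genetic Effects on Offspring Traits via Bayesian Animal
    Models and Maternal GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying maternal genetic effects on offspring
    phenotypes in pedigreed populations.  Provides pedigree validation,
    inbreeding and additive-relationship machinery (including the sparse
    inverse by Henderson's rules), Gibbs samplers for five univariate and
    bivariate animal models combining direct genetic, maternal genetic,
    common-litter and maternal-environment effects, and a BayesB maternal
    genome-wide association analysis in which dam genotypes are regressed
    on offspring phenotypes, with 1-Mb window variance shares, per-SNP
    Bayes factors and window-to-gene annotation.  A synthetic-data
    generator emulating a divergent-selection rabbit design makes every
    stage testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
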