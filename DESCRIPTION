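Package: swinegs
Title: Genomic Evaluation for Pig Breeding with Bayesian Whole-Genome Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genomic evaluation in pig breeding
    programs: SNP panel quality control, pedigree relationship matrices and
    K-means cross-validation folds that minimise train/test relatedness,
    pedigree BLUP estimated breeding values, deregression of EBVs into
    genomic-model response variables with Garrick weights, weighted BayesB
    and BayesC Gibbs samplers for marker effects, 1-Mb-window genetic
    variance GWAS with Bayes factors, and relationship-clustered
    cross-validated genomic prediction. A synthetic data module simulates
    multi-generation pedigrees, gene-dropped genotypes with optional LD
    blocks, and quantitative traits with litter and contemporary-group
    effects so every stage can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
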