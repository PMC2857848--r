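Package: gebvtools
Title: Bayesian Shrinkage Methods for Genomic Breeding Value Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome regression for genomic selection with three
    Bayesian shrinkage priors on marker effects (Bayes-A with fixed
    scaled inverse chi-square hyperparameters, a Student-t generalization
    that estimates scale and degrees of freedom from the data, and a
    Bayesian Lasso with exponential priors on per-marker variances),
    fitted by Gibbs sampling with Gauss-Seidel residual updates.
    Supporting machinery covers simulation of livestock-like full-sib
    populations with SNP genotypes and growth phenotypes, Gompertz and
    logistic growth-curve fitting with AIC/BIC model selection,
    pedigree-based BLUP via Henderson's mixed-model equations,
    single-locus genotype probabilities from iterative peeling, and
    low-density SNP panel prediction scenarios with expected-genotype
    coding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
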