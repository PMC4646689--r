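Package: pedliab
Title: Pedigree-Based Liability-Threshold Models for Binary Traits in Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for family-study epidemiology and heritability of binary
    (disease) traits on extended pedigrees. Computes the numerator relationship
    (A) matrix and its sparse inverse from pedigrees, fits Bayesian
    liability-threshold animal models (univariate, bivariate-by-sex, and
    three-category latent-trait models) by Gibbs sampling with truncated-normal
    or Polya-Gamma data augmentation, derives liability-scale heritability,
    genetic and family-environment correlations, HPD intervals, pMCMC and odds
    ratios, estimates family-jackknifed kinship correlations, post-stratifies
    sample estimates to population frequencies, corrects retrospective lifetime
    prevalence toward a cumulative design, and simulates family-study datasets
    with known variance components for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    survival,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
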