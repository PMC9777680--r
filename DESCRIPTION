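Package: compnetlasso
Title: Multi-Task Sparse Network Lasso for Compositional Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Regression for compositional covariates (microbiome relative
    abundances and similar simplex-valued data) in which every sample carries
    its own zero-sum log-contrast coefficient vector. A network lasso penalty
    over a sample-similarity graph fuses coefficient vectors of related
    samples into latent clusters while an L1 penalty selects features;
    estimation is by ADMM with closed-form updates. Coefficients for unseen
    samples are obtained as the constrained weighted geometric median (Weber
    problem) of the fitted vectors. Includes compositional preprocessing
    (zero replacement, closure, log and centered log-ratio transforms,
    phylogenetic feature agglomeration by cophenetic distance), k-nearest
    neighbour relation graphs from Gower or Aitchison log-ratio distances,
    cross-validation for the regularization parameters, a compositional
    lasso baseline, and a seeded simulation-study engine with
    logistic-normal composition generation and graph corruption.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports:
    stats,
    utils,
    MASS,
    ape,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
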