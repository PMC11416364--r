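Package: symregpk
Title: Symbolic Regression Networks for Pharmacometric Covariate Models
Version: 0.1.0
Authors@R:
    person("symregpk", "developers", email = "symregpk@example.org", role = c("aut", "cre"))
Description: Learns human-readable covariate model structures for compartmental
    pharmacokinetic models by training small symbolic regression networks
    through an exact, differentiable simulator of the three-compartment
    mammillary model, and sparsifying them with Hessian-diagonal (salience)
    pruning. Provides the median absolute logarithmic error loss and related
    predictive-performance metrics, covariate-free baseline models bracketing
    achievable performance, a synthetic cohort generator emulating a propofol
    infusion study, expression extraction with plain-text and LaTeX rendering,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
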