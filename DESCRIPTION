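Package: layerwalk
Title: Likelihood Inference for Diffusion in Layered Media from First-Exit Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the practical identifiability of per-layer
    hopping rates in a one-dimensional layered lattice random walk from
    first-exit-time data. Provides a seeded stochastic walk simulator, the
    exact exit-time distribution and likelihood via the absorbing Markov
    chain, a moment-matched Gamma approximate likelihood built on
    continuum-limit exit-time moments, maximum-likelihood fitting with
    univariate and bivariate profile likelihoods and chi-squared calibrated
    confidence intervals, simulated coverage studies, and model reduction by
    partial homogenization of adjacent layers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
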