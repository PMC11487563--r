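Package: boldhrf
Title: Linear and Biophysical Models of the Ageing BOLD Impulse Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the BOLD haemodynamic response function
    (HRF) and its change across the adult lifespan. Implements an m-sequence
    event design generator, finite impulse response (FIR) and canonical
    two-gamma basis sets with prewhitened first-level general linear models
    (AR(1)+white-noise restricted maximum likelihood), nonlinear four-parameter
    template fitting of individual HRFs, a biophysical balloon-type hemodynamic
    model inverted per participant by Variational Laplace, group-level
    Parametric Empirical Bayes with Bayesian Model Reduction, Volterra-kernel
    summaries of haemodynamic nonlinearity, HRF shape features, and
    cross-validated age prediction. A synthetic-cohort generator with known
    age-dependent neurovascular parameters provides a ground-truth test
    surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
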