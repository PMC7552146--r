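Package: methaphen
Title: Infrared-Predicted Enteric Methane Phenotypes and Their Genetic Parameters
Version: 0.1.0
Authors@R:
    person("Methaphen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving enteric methane emission (EME) phenotypes of
    dairy cows from milk fatty-acid profiles, calibrating whole-spectrum
    Bayesian (BayesB) prediction equations on Fourier-transform infrared
    (FTIR) milk spectra with repeated training-testing validation, and
    estimating genetic parameters (heritabilities, herd/date variance
    fractions, genetic/herd/residual/phenotypic correlations) with Bayesian
    pedigree-based animal models fitted by Gibbs sampling. Includes a
    synthetic-data generator (pedigrees, herd structure, milk records and
    spectra with known variance partitions) so the whole pipeline is testable
    without access to survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
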