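Package: stpem
Title: Quantal Analysis of Repetitive Synaptic Transmission by Exact
    Expectation-Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative modelling of stochastic repetitive transmission at
    chemical synapses.  Implements the stochastic Tsodyks-Markram quantal
    model (binomial release from a finite pool of depleting release sites,
    facilitating release probability, inverse-Gaussian quantal amplitudes,
    additive Gaussian baseline noise), an exact forward-backward likelihood
    engine over the hidden release-site counts, an expectation-maximization
    estimator of the quantal and dynamic parameters, Fisher-information
    analysis of stimulation protocols via Cramer-Rao bounds, a conventional
    least-squares baseline with condition-number diagnostics, estimator
    validation tools (parametric bootstrap, leave-one-out predictive checks,
    position-preserving shuffles), and preprocessing of raw postsynaptic
    voltage traces into response amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
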