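Package: synquant
Title: Bayesian Quantal Analysis of Synaptic Amplitude Trains with Correlated Vesicle Release
Version: 0.1.0
Authors@R: person("Synquant", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact Bayesian inference of quantal and short-term-plasticity
    parameters from trains of postsynaptic-potential amplitudes. The
    likelihood of an amplitude train is computed exactly as a scaled matrix
    product over the hidden vesicle-site occupancy (a forward algorithm),
    retaining the serial correlations induced by vesicle depletion.
    Includes a Tsodyks-Markram style depression-facilitation release
    model, a gamma-Gaussian convolution observation model, a
    grid-discretised Metropolis-Hastings sampler with flat priors, an
    uncorrelated factorised baseline likelihood, and a stochastic synapse
    simulator for synthetic data, validation and Monte-Carlo oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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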