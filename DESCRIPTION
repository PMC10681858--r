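Package: stochcirc
Title: Stochastic Simulation, Calibration and Automated Design of Gene
    Regulatory Circuits
Version: 0.1.0
Authors@R: person("stochcirc", "developers", role = c("aut", "cre"),
    email = "stochcirc@example.org")
Description: Tools for gene regulatory circuits in the stochastic regime.
    Simulates circuit dynamics either exactly, with a Gillespie stochastic
    simulation algorithm over the transcription-translation-degradation
    reaction network, or through a semi-Lagrangian solver for the partial
    integro-differential equation that approximates the chemical master
    equation of bursty protein expression. On top of the simulators the
    package provides maximum-likelihood calibration of kinetic parameters
    from histogram time-series data via Kullback-Leibler divergence, and
    automated design of circuit topology and parameters as a mixed-integer
    nonlinear program solved by a scatter-search global optimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
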