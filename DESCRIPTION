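Package: burstsim
Title: Burst-Aware Langevin and Gillespie Simulation of Stochastic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of the three-stage gene expression model
    (telegraph gene activation, transcription, translation) with explicit
    transcriptional and translational bursting. Provides closed-form burst
    statistics (geometric burst sizes, Poisson and compound burst events),
    steady-state means and variances from the linear noise approximation and
    from regime-specific burst approximations, an exact Gillespie (direct
    method) reference simulator, and an adaptive-step burst Langevin
    integrator with tau-leaping step-size selection, critical-reaction
    interleaving, half-tau retries and a negative-production accumulator.
    Includes a two-gene Hill-repression network with leak transcription and
    experiment drivers that compare the Langevin scheme against the exact
    simulator on steady-state ensembles, parameter grids and switching
    dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
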