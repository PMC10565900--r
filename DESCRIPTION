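Package: cheatcycles
Title: Cheat-Cooperator Dynamics Under Serial Passage and Stochastic Group
    Formation
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the eco-evolutionary dynamics
    of a cooperator strain and a social cheat. Implements two-strain
    competitive Lotka-Volterra growth with sigmoid density- and
    frequency-dependent cheat fitness, deterministic serial-passage
    experiments with periodic dilution bottlenecks, and an individual-based
    metapopulation with random pairwise group mixing and integer-count
    demographic stochasticity. Includes harmonic regression and discrete
    Fourier transform statistics for detecting within-cycle and cross-cycle
    oscillations in cheat proportion, relative-fitness summaries, and
    parameter-sweep utilities, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
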