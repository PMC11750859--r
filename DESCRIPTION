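Package: mossyburst
Title: Compartmental Simulation of Ectopic Afterdischarge in Mossy-Fiber Axons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A compartmental cable-equation simulator for hippocampal
    mossy-fiber axons modeled as a chain of soma, axonal cylinders and en
    passant boutons, with declarative Hodgkin-Huxley style channel kinetics.
    Implements an implicit (backward Euler) tridiagonal solver with staggered
    exponential gating updates, stimulation-protocol presets for
    repetitive-stimulation experiments with local leak-reversal
    depolarization, and trace-analysis tools for spike detection,
    action-potential half-duration, afterdischarge statistics, dV/dt
    inflection counting and multi-site latency ordering. Includes a
    synthetic-trace fixture generator and analytic passive references so
    every analysis stage is testable against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
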