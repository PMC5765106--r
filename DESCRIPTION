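Package: phasewta
Title: Winner-Take-All Dynamics in Adaptive Star Networks of Phase Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a star network of phase oscillators in
    which peripheral oscillators compete for synchronization with a central
    oscillator whose natural frequency and incoming coupling amplitudes adapt
    over time. Provides the parametric 2*pi-periodic interaction functions with
    axiom checking, compiled adaptive Runge-Kutta integration of the full and
    phase-difference systems, enumeration and closed-form stability analysis of
    the symmetric and perturbed winner-take-all equilibria, prediction and
    detection of stationary and rotating (limit-cycle and torus) winner-take-all
    regimes arising through saddle-node bifurcations on invariant circles and
    tori, and a seeded Monte-Carlo experiment protocol that classifies
    competition outcomes over repeated randomized runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
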