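Package: crncontrol
Title: Chemical Reaction Network Compilation and Biomolecular Tracking Control
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing embedded biomolecular reference-tracking
    controllers from chemical reaction networks (CRNs). Provides a mass-action
    CRN compiler with a stiff deterministic simulator, a library of biomolecular
    arithmetic operator motifs (gain, summation, one-sided subtraction,
    division, integration, and dual-rail two-sided arithmetic), synthesis of an
    inverse-feedforward plus proportional-integral controller for an enzymatic
    reaction process (full and Taylor-simplified forms), robustness and
    sensitivity analyses (Chernoff-sized Monte Carlo, one-at-a-time parameter
    sweeps, process-regime sweeps, retroactivity), and a compiler from abstract
    uni/bimolecular reactions to DNA strand-displacement implementations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
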