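Package: BlochRiccati
Title: Exact Analytical Bloch-Equation Propagators for Frequency-Modulated RF Pulses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form propagation of nuclear magnetization through
    hyperbolic-secant (HS1), chirp, and square radiofrequency pulses in the
    relaxation-free rotating frame. The Bloch equation is mapped by
    stereographic projection onto the extended complex plane, where the
    resulting Bloch-Riccati equation admits exact solutions in terms of Gauss
    and confluent hypergeometric functions with complex parameters. A single
    integration constant anchors the particular solution to any known
    magnetization, which permits arbitrary initial states, resonance offsets,
    asymmetric pulse truncation, and chaining across composite pulses such as
    BIR-4. A fixed-step fourth-order Runge-Kutta integrator of the same Bloch
    equation is included as an independent verification oracle, together with
    a frame-independent angular error metric, convergence reporting, pulse
    shape export, and a configuration-driven command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'BlochRiccati-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'projection.R'
    'pulse-models.R'
    'hs1-analytic.R'
    'chirp-square-analytic.R'
    'rk4.R'
    'composite.R'
    'io.R'
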