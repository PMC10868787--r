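Package: oscmem
Title: Phase-Coded Working Memory in Oscillator-Driven Low-Rank Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how recurrent neural networks store working
    memories in the phase of neural oscillations. The package trains rank-two
    (and full-rank) rate networks on a phase-coding task driven by a theta-band
    reference oscillation, generates synthetic theta-like reference signals
    emulating hippocampal local field potentials, and reverse engineers the
    trained dynamics: reduction to an autonomous system on the (kappa1, kappa2,
    theta) torus, limit-cycle location via Poincare return maps, orbital
    stability via Floquet multipliers of the monodromy matrix, stimulus and
    amplitude-frequency bifurcation scans with m:n locking classification,
    reduction to two phase-coupled oscillators with an extracted coupling
    function, and mean-field models with Gaussian-mixture connectivity,
    including hand-designed multi-population presets and mixture fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
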