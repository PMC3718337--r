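Package: simmswitch
Title: Bistable Switch Motifs for Cell Cycle Checkpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action ordinary differential equation models of the
    substrate-inhibitor-multiply-modified (SIMM) bistable switch motif and
    its cell-cycle instantiations: the generic SIMM and simplified SIMM*
    motifs, a total quasi-steady-state (TQSSA) reduction, the Sic1-Clb and
    Cln-Sic1-Clb models of the budding-yeast G1/S transition, and the
    MCC-APC and CycB-MCC-APC models of the mitotic (spindle assembly)
    checkpoint. Provides multi-start steady-state location with stability
    classification, saddle-node (fold) detection for signal-response
    curves, two-parameter control-plane mapping of bistable regions,
    hysteresis and irreversibility protocols, checkpoint-release
    time-course scenarios, robustness scans, and read/write support for a
    restricted XPPAUT .ode dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
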