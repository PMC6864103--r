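Package: microca
Title: Compartmental Modeling of ER-Mitochondria Microdomain Calcium Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-cell, four-compartment model of IP3-induced calcium
    dynamics in non-excitable cells with an explicit ER-mitochondria
    microdomain compartment.  Channel connectivity coefficients distribute
    IP3R, SERCA, MCU and mNCX activity between the bulk cytosol and the
    microdomain.  The package provides protocol-driven stiff integration
    (resting-state equilibration, IP3 step stimulation, compartment
    inactivation, MCU knockout, flux clamping), oscillation feature
    extraction and mechanism classification, brute-force bifurcation and
    response scans over stimulation level, connectivity and ER-mitochondria
    distance, and global sensitivity analysis by Latin hypercube sampling
    with partial rank correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
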