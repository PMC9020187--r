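Package: cgresin
Title: Coarse-Grained Simulation of Photopolymerizable Dental Resins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained coarse-grained molecular simulator for
    Bis-GMA/TEGDMA photopolymer resins. Provides Martini-3-style bead
    templates for the two monomers with harmonic bond, angle, periodic
    dihedral and improper terms and ring constraints; random packing of
    formulation boxes; a velocity-Verlet molecular dynamics engine with
    stochastic velocity-rescaling thermostat, weak-coupling barostat and
    SHAKE constraints; a simulated chain-growth polymerization algorithm
    (cutoff-criterion bonding with active-label transfer); and analyses
    for density, volumetric curing shrinkage, double-bond conversion,
    bonded distributions and glass-transition estimation from
    density-temperature sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
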