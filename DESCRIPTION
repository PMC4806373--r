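Package: cuticleflux
Title: Finite-Dose Penetration Kinetics of Hydrophobic Pollutants Through
    Plant Cuticular Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for unsteady-state (finite-dose) diffusion-cell studies of
    hydrophobic organic pollutants penetrating isolated plant cuticular
    membranes. Provides a three-compartment (epicuticular waxes, cuticle
    proper, cuticular layer) five-pool kinetic simulator with sampling-loss
    bookkeeping and temperature programming, loss-corrected penetration
    estimators (cumulative penetrated mass per area, phase segmentation,
    maximal penetration rate, hold-up time, penetration coefficient,
    dose-response and temperature-segment regressions), a sorption-equilibrium
    mass-balance inversion of solution time courses into per-compartment
    amounts and densities with a four-interface flux decomposition, a seeded
    synthetic-experiment generator with presets emulating published
    diffusion-cell designs, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
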