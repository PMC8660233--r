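Package: gradfss
Title: Wall Fluid Shear Stress on Adherent Cells in a Gradient Flow Chamber
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for wall fluid shear stress
    (FSS) on adherent cells in a wedge-shaped (gradient) parallel-plate flow
    chamber. Provides the chamber background flow (lubrication closed form
    and a fully developed cross-section solve), a staggered-grid Stokes
    solver with volume penalization for the local viscous flow around
    spherical-cap cells (isolated or hexagonally packed), a compressible
    neo-Hookean model of the cell loaded one-way by the fluid traction, and
    sector/band polarization statistics (RAV) of the FSS field on the cell
    surface, together with a synthetic-field generator so every analytics
    stage is testable without a PDE solve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
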