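Package: mavessel
Title: Particle-Based Simulation of Blood Cell Transport in Retinal
    Microaneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mesoscale simulation of blood flow in retinal capillaries
    bearing saccular microaneurysms. Blood plasma is modelled with
    dissipative particle dynamics (DPD); red blood cells and platelets are
    explicit closed triangulated membranes carrying worm-like-chain elastic
    bonds, dihedral bending stiffness and global area/volume constraints,
    with optional Morse-potential cell-cell adhesion to emulate
    fibrinogen-mediated rouleau formation in diabetic blood. Channel
    geometries are parameterised by the body-to-neck ratio of the aneurysm.
    The package builds the geometries and cell meshes, runs the coupled
    fluid-membrane dynamics with no-slip bounce-back walls and
    pressure-gradient driving, and reduces the resulting cell tracks to the
    transport statistics used to characterise thrombosis-prone conditions:
    the probability that a platelet passing the channel segment migrates
    into the aneurysm lumen, and its residence time inside.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
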