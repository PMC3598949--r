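Package: eruptsim
Title: Finite Element Analysis of Bite-Force-Driven Tooth Eruption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale linear-elastic finite element pipeline for studying
    how functional bite forces load the soft-tissue dental follicle around
    unerupted teeth. Generates labelled tooth-in-crypt tetrahedral meshes,
    assembles and solves constant-strain tetrahedron elasticity problems under
    muscle-derived load cases, recovers per-element hydrostatic stress and
    equivalent strain, and runs the follicle cap analysis: 3 mm coronal and
    apical soft-tissue caps, compression/tension percentages by volume and by
    biological response unit (BRU, hydrostatic stress times element volume,
    N mm), binned distributions, pooling across erupting teeth, and exception
    classification against the coronal-compression / apical-tension pattern.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
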