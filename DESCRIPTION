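Package: cgfrac
Title: Coarse-Grained Fracture Dynamics of Biomimetic Apatite-Collagen Composites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Particle-based coarse-grained simulation of deformation and
    fracture in enamel-like apatite-collagen composites. Building blocks
    (one collagen triple-helix plus a block of hydroxyapatite unit cells)
    sit on a 2-D hexagonal lattice and interact through truncated-harmonic
    pair potentials that encode both elasticity and brittle bond rupture.
    Pristine blocks switch irreversibly to a softer, longer-equilibrium
    damaged species when a bonded neighbour separates beyond the pristine
    rupture cutoff. The package builds lattices with surface notches,
    applies strain-and-hold loading, integrates Langevin dynamics with a
    compiled core, records virial stress and switching events, clusters
    broken bonds into micro-cracks with percolation analysis, fits
    exponential stress relaxation, and fits truncated-harmonic potentials
    to tabulated energy-distance profiles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
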