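Package: memmodes
Title: Membrane Binding-Mode Analysis for Peripheral Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising how a peripheral membrane
    protein sits on a lipid bilayer.  Classifies trajectories into binding
    modes from protein-lipid contact fingerprints, estimates protein altitude
    above the phosphorus plane, deconvolves AFM particle-height distributions
    into Gaussian populations, converts state populations into Boltzmann
    energy diagrams with allowed transition paths, and backmaps coarse-grained
    poses onto atomistic reference structures by rigid superposition.  Ships
    seedable synthetic-data generators (bilayer patches, bound-protein
    trajectories, AFM height fields) with planted ground truth so every
    estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
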