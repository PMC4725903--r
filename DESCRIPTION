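Package: msclattice
Title: Bilayer-Mediated Assembly and Gating of Mechanosensitive Channel Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-elastic modelling of bilayer-thickness-mediated
    interactions between mechanosensitive channels (MscL). Solves the
    bilayer thickness-deformation energy around anisotropic protein
    footprints with a mixed discrete-Kirchhoff-triangle / linear-triangle
    finite-element formulation on unstructured meshes, tabulates
    orientation-dependent pair potentials and steric minimum distances,
    assembles protein lattices by Metropolis Monte Carlo with simulated
    annealing, ranks candidate lattice architectures for tetrameric and
    pentameric channels, and computes lattice activation barriers and
    Arrhenius gating-rate ratios under membrane tension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    interp,
    deldir,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
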