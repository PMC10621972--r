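Package: efdangio
Title: Ellipsoidal Fibril Distribution Fields for Simulating Matrix-Guided
    Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for representing extracellular-matrix collagen anisotropy as
    deformable three-dimensional ellipsoidal fibril distributions (EFDs) and for
    simulating discrete, stochastically growing microvessel networks guided by
    those fields. Provides symmetric positive-definite structure-tensor algebra
    and anisotropy metrics, discretized orientation distribution functions on
    subdivided icosahedral spheres with generalized fractional anisotropy and
    Fisher-Rao distances, pseudo-deformation of EFDs by polar decomposition with
    a verification harness against true point-mapped deformation, Monte-Carlo
    sampling of fibril directions, Log-Euclidean interpolation of tensor fields
    on hexahedral grids, an agent-based sprouting-angiogenesis growth engine
    with density- and anisotropy-dependent extension rates and stochastic
    branching, procedural builders for uniform-culture, anisotropy-gradient and
    tumor-interface scenarios, and network morphometry with replicate
    orchestration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
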