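Package: morphospectra
Title: Spectral Decomposition of Whole-Embryo Surface Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies whole-embryo morphogenesis from time-lapse surface
    meshes. A fixed-topology icosphere is deformed onto each frame of a
    closed, genus-0 embryo surface by distance minimization, yielding
    Lagrangian surface markers. Marker trajectories give a velocity field
    whose symmetric tangential gradient is the surface strain-rate tensor;
    its eigenvalue norm defines a scalar morphological-activity field. The
    field is decomposed spatially into spherical harmonics and each harmonic
    coefficient time series into Ricker-wavelet scalograms, exposing the
    principal morphogenetic modes and their timing. Includes a synthetic
    deforming-embryo generator (radial harmonic modes, division-like global
    pulses, invagination-like polar indentation, cell tessellations with
    3-cell junctions) providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
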