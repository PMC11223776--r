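Package: adipoinvade
Title: Discrete-Element Simulation of Breast Cancer Cell Invasion into
    Adipose Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates breast cancer cells invading confluent adipose tissue
    using the discrete element method. Adipocytes are three-dimensional
    deformable particles (triangulated closed surfaces with harmonic volume
    and per-face area penalties), cancer cells are active, cohesive soft
    spheres, and the system is confined between a static wall and a mobile
    wall that imposes constant pressure. Includes jammed-packing generation
    by athermal quasistatic compression with FIRE energy minimization,
    extracellular-matrix tethering spring networks, a radical Voronoi
    (Laguerre) tessellation for the cancer-adipocyte interfacial area, and
    the analysis pipeline for the normalized degree of invasion, velocity
    decorrelation times, sigmoid fits, and the dimensionless energy-scale
    collapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
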