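Package: cellstretch
Title: Finite-Element Simulation of Extensometer Experiments on Plant Epidermal Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds idealized three-dimensional cellular monolayer templates that
    emulate onion epidermal peels, models the cell walls as hyperelastic
    Saint Venant-Kirchhoff membranes (isotropic on Biot strain or transversely
    isotropic on Green-Lagrange strain), pressurizes the cells with a turgor
    follower load, and simulates microextensometer stretching by incremental
    Dirichlet displacement of the template ends with reaction-force logging.
    Includes normalization of force-displacement output to stress-strain
    curves, extraction of reference-strain stresses and tissue stiffness
    anisotropy ratios, and fitting of the cell-wall longitudinal/transverse
    modulus fraction to a target tissue-level ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
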