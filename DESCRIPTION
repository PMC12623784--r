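Package: septring
Title: Mechanistic Models of Cdc42 Polarization and Septin Ring Assembly in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional mechanistic models of Cdc42 GTPase polarization
    and septin ring self-assembly on the budding-yeast plasma membrane.
    Surface reaction-diffusion systems on triangulated spheres are coupled to a
    well-mixed cytosol and advanced with an implicit-explicit finite-element
    scheme; a stochastic exocytosis engine displaces membrane species radially
    from vesicle fusion sites and delivers cargo. The package also provides
    particle-based simulators of exocytosis-driven displacement, quantification
    of cluster area, septin ring diameter and log-log volume-scaling exponents,
    experiment pipelines for volume-scaling and exocytosis perturbation
    studies, and a synthetic fluorescence-microscopy generator with
    ground-truth-based image quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
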