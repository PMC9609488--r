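Package: fibrenet
Title: Stochastic Generation and Characterization of Fibrous Biomaterial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates three-dimensional stochastic fiber networks that
    reproduce prescribed fiber diameter, length, orientation, and tortuosity
    distributions, as found in fibrous biomaterials such as fibrin clots,
    collagen gels, and nonwoven fabrics. Provides de la Vallee Poussin
    orientation kernels with a projection-distortion correction relating 2D
    (imaged) to 3D orientation strengths, calibrated von Mises-Fisher random
    walks for fiber tortuosity, damped bead-spring dynamics to enforce fiber
    non-penetration, and watershed pore-size analysis on a periodic voxel
    grid with closed-form mean-pore-size predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
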