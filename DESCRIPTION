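Package: manifoldRemap
Title: Geometry of Cross-Context Neural Manifold Remapping and Cerebellar
    Expansion-Recoding Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how simultaneously recorded neural
    populations reorient low-dimensional activity manifolds across behavioral
    contexts, and for simulating cerebellar granule-layer architectures in a
    continual-learning setting. Provides a synthetic two-context session
    generator with planted latent rotations and calibrated split-half
    reliability; trial averaging, Spearman-Brown reliability correction and
    joint-reliability filtering; per-task and joint-task PCA with
    participation-ratio dimensionality; Procrustes rotation, isoperimetric
    circularity/elongation and temporal-covariance representational similarity
    analysis; canonical-correlation communicating subspaces, cross-population
    regression transfer and linear discriminant state decoding; and a
    Relay/Expansion/Rotation granule-layer network comparison with an
    alternating two-task curriculum, learning-speed fits, previous-task
    interference, Jaccard overlap and an input-geometry shattering control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    Rcpp,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
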