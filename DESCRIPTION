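Package: usinr
Title: Implicit Neural Representations for 3D Ultrasound Reconstruction
    from Rotational Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs continuous 3D ultrasound volumes from sparse 2D
    B-mode slices acquired on a known rotational sweep. Provides a synthetic
    rotating sphere-phantom simulator with speckle and exact masks, a dual
    intensity/segmentation coordinate network (SIREN multilayer perceptron
    with harmonic positional encoding), structural-similarity and
    Dice/cross-entropy training objectives with Adam, cosine annealing and
    gradient EMA filtering, arbitrary-coordinate volume sampling and
    reslicing, an exact k-d tree nearest-neighbour baseline, 3D connected
    component labelling, convex-hull volumetry, and contrast / overlap /
    volume-error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
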