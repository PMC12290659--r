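Package: PLItexture
Title: Self-Supervised Texture Representations for 3D Polarized Light Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for learning and evaluating texture representations of
    nerve-fiber architecture in 3D polarized light imaging (3D-PLI). The
    package implements the 3D-PLI physical signal model (forward simulation
    and harmonic Fourier parameter retrieval), a synthetic multi-section
    phantom generator with ground-truth tissue labels and cortical
    morphology, an augmentation algebra that transforms transmittance,
    direction and retardation maps jointly and consistently, spatial context
    sampling of positive pairs within and across sections, a SimCLR-style
    contrastive learner built on a width-reduced 50-layer residual encoder
    with InfoNCE loss, classical texture baselines (histogram statistics,
    local binary patterns, grey-level co-occurrence matrices on a circular
    Sobel direction-gradient map), and a downstream evaluation suite
    covering PCA component maps, two-step clustering with cross-section
    IoU, linear probing, ridge regression of cortical morphology, and
    RBF-kernel retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    cluster,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
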