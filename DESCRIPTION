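Package: vascuflow
Title: Morpho-Functional Analysis of Cerebrovascular Networks from
    Doppler Optical Coherence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An acquisition-to-analysis pipeline for morpho-functional
    cerebrovascular optical coherence microscopy (OCM).  Per-voxel
    M-mode OCT time series are converted into Doppler power spectra by
    the joint spectral and time domain (jSTdOCT) approach, fitted with a
    wrap-aware Gaussian model, and mapped to signed axial, transverse
    and total blood-flow velocities.  Binary vessel segmentations are
    skeletonized into annotated vascular graphs carrying per-segment
    diameters, velocities, flow directions, artery/vein labels,
    branching orders and arteriovenous path statistics.  Missing segment
    velocities are recovered by enforcing conservation of mass at
    bifurcations.  A synthetic vasculature generator with Poiseuille
    flows and an OCT signal simulator provide ground-truth test
    substrates for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    igraph,
    Matrix,
    minpack.lm,
    signal,
    jsonlite,
    tiff,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
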