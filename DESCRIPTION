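Package: patchdyn
Title: Quantitative Analysis of Bacterial MreB Patch Dynamics from TIRF Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of membrane-associated MreB
    patch dynamics in rod-shaped bacteria imaged by total internal reflection
    fluorescence (TIRF) microscopy. Provides a synthetic movie generator with
    ground truth (directed circumferential, Brownian and confined patch
    motion on a cylindrical cell, evanescent-field visibility, Gaussian PSF
    rendering with shot and camera noise), difference-of-Gaussians plus
    watershed spot detection, Otsu cell segmentation, gated frame-to-frame
    single-particle tracking, mean-squared-displacement motion classification
    (directed, random, constrained, unclassified), diffusion estimation from
    cumulative displacement distributions, per-cell dynamic statistics with
    bootstrap standard errors, geometric models linking directed patch motion
    to sidewall elongation (full turns per generation and inserted
    peptidoglycan band width), and an event-level lattice simulator of the
    3-for-1 and 3-under-2 glycan-insertion models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
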