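Package: bouton3d
Title: Automated 3D Quantification of Synaptic Boutons in Fluorescence
    Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and counts synaptic boutons (microglomeruli) in 3D
    fluorescence microscopy stacks. Provides Richardson-Lucy maximum-
    likelihood deconvolution with a bead-measured or parametric Gaussian
    point spread function, multiple-threshold segmentation with
    cross-threshold merging of object centers, analytic corrections for
    axial signal leakage and for boundary over-counting in small regions
    of interest, a surface-scaling model of the count-versus-volume
    relationship, and running-average 3D density maps. Includes a
    synthetic-stack generator with known ground truth (hard-core bouton
    fields, anisotropic blur, depth-dependent attenuation, Poisson noise)
    so the whole pipeline is testable without microscope data, and a
    command-line interface wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
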