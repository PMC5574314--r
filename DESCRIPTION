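Package: mitoquant
Title: Ratiometric Fluorescence Quantification of Mitochondrial Membrane
    Potential, Mass and Cytosolic Redox State
Version: 0.1.0
Authors@R:
    person("Mitoquant", "Developers", email = "mitoquant@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for subcellular ratiometric fluorescence
    microscopy of cultured astrocytes. Computes emission-ratiometric JC-1
    images reporting mitochondrial membrane potential, detects and measures
    single mitochondria (deconvolution, focal-plane collapse, thresholding,
    spatial filtering, skeleton-based morphometry), derives per-cell
    mitochondrial mass and density, quantifies cytosolic redox state from
    roGFP1 excitation-ratio series (degree of oxidation and Nernst reduction
    potential), characterizes the microscope point spread function from
    sub-resolution bead stacks, and provides the group-comparison statistics
    used for genotype and drug contrasts. A ground-truthed synthetic
    microscopy generator makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
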