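Package: spotscreen
Title: Spatially Aware Quality Control for Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for spot- and bin-based spatial transcriptomics
    (10x Genomics Visium and Visium HD style grids) that scores each spot
    against its k nearest spatial neighbours instead of the whole tissue.
    Computes per-spot robust local z-scores (modified z: 0.6745 times the
    deviation from the neighbourhood median, scaled by the neighbourhood
    median absolute deviation) for standard QC metrics (total UMI counts,
    detected genes, mitochondrial percentage), flags directional outliers,
    and contrasts them with the conventional tissue-wide median +/- n MAD
    baseline. Includes readers for 10x-style matrix directories and
    h5ad-style annotated matrices, a synthetic hexagonal/square tissue
    generator with ground-truth artifacts (micro-tears, low-count regions,
    mitochondrial spikes), spatial QC plots with multipage PDF reports, and
    a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    rhdf5,
    optparse,
    parallel
Suggests:
    testthat (>= 3.0.0),
    RANN
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
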