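Package: muridens
Title: Automated Lung Segmentation and Densitometry for Murine Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated analysis pipeline for thoracic micro-CT scans of
    murine pulmonary-fibrosis models. The pipeline coarsely localizes lungs,
    heart and airways on down-sampled axial slices, derives a linear grey-level
    to Hounsfield-unit transfer function from the airway and heart segmentations,
    crops a fixed-size region of interest around the lungs, segments the left and
    right lungs with three orthogonal single-view models fused by per-voxel
    majority voting, and quantifies aeration compartments (hyper-inflated,
    normo-aerated, hypo-aerated, non-aerated) by Hounsfield-unit densitometry.
    Ships a synthetic murine-thorax phantom generator with ground-truth labels
    and graded fibrotic involvement so that every stage is testable end to end
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
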