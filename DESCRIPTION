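Package: priorseg
Title: A Priori Guided Level-Set Segmentation of CT Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential slice-to-slice segmentation of organ regions in CT
    image volumes. Starting from one manually delineated seed slice, the
    method accumulates per-slice intensity statistics (mean and standard
    deviation of the segmented region), converts them into a voting-resolved
    probability density map over a search region derived from the previous
    slice's mask, and drives a modified distance-regularized level-set
    evolution in two phases: a fast balloon phase weighted by the probability
    map, followed by an edge-dominated refinement phase. Includes Dice /
    false-positive / false-negative evaluation, a synthetic phantom generator
    with ground truth for validation, and readers/writers for NIfTI volumes
    and PNG/TIFF slice stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
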