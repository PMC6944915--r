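Package: recoverkit
Title: Quantitative Pipelines for G2 Checkpoint-Recovery Screens, Radiation-Induced
    Foci, and Repair-Junction Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and image-analysis tooling for studies of recovery from
    the DNA-damage-induced G2 checkpoint. Implements Z-score based hit calling for
    multi-plate siRNA screens with asymmetric cutoffs and per-oligo deconvolution
    against negative-control wells; relative-mitotic-entry, clonogenic-survival and
    reporter repair-efficiency normalizations; an automated detector for ionizing
    radiation-induced gammaH2AX/53BP1 foci (DAPI nucleus segmentation by
    median-filter/threshold/watershed, maximum-intensity projection,
    Difference-of-Gaussians background subtraction, and an adaptive two-criterion
    pixel rule); and a classifier for I-SceI reporter repair junctions into direct
    re-ligation, deletion, delins and insertion events with deletion-size and
    microhomology spectra. Ground-truthed simulators for screens, microscopy scenes
    and junction reads make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
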