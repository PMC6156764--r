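Package: prolifscan
Title: Single-Cell Proliferation Quantification from Three-Channel
    Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated single-cell image analysis for EdU proliferation
    assays on transfected cells. Segments nuclei from DAPI images with a
    difference-of-Gaussian filter, k-means adaptive thresholding and a
    distance-transform (hybrid) watershed; measures Flag and EdU signals
    per nucleus; selects the transfection-intensity threshold from the
    marker distribution; computes condition-level proliferation rates and
    runs the Levene/ANOVA/Tukey comparison chain. Includes a synthetic
    three-channel field generator with exported ground truth, plus small
    auxiliary assay computations (delta-delta-Ct fold change, co-IP
    densitometry normalization, luciferase normalization, spreading-area
    classification, alanine-cassette mutant design, docking-model contact
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    car,
    bio3d,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
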