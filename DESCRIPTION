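Package: lignoquant
Title: Quantification of Cell-Wall Fluorescence and Lumen Morphology in
    Wood Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of cell-wall autofluorescence and
    cell-lumen morphology (area, perimeter, circularity) from
    multi-exposure fluorescence macrographs of wood transverse sections.
    Implements contrast normalisation (CLAHE), the Huang, Li, Moments and
    Minimum histogram auto-thresholds, connected-component particle
    morphometry with species-specific size filters (spruce tracheids,
    beechwood vessels), mean wall-intensity measurement along an exposure
    series, and a calibrated synthetic section generator with per-lumen
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: ImageAnalysis, CellBiology, Software
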