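Package: nociquant
Title: Quantification Pipelines for Drosophila Larval Nociception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image quantification and statistics for larval nociception
    studies: nuclear pMad immunofluorescence measurement with four-corner
    background subtraction and control normalization, axon-terminal
    morphometry of single-cell flip-out clones (Otsu binarization,
    neuromere-normalized terminal area, entry-aligned projection heat maps),
    GCaMP delta-F/F0 analysis against an asynchronously logged thermal-ramp
    stimulus with 1 degree C binning, and nonparametric behavioral statistics
    including Steel's many-to-one rank test. A synthetic-data module
    generates soma images, clone images, calcium recordings and behavior
    tables with known ground truth so that every pipeline stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
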