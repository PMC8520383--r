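Package: retline
Title: Multi-Scale Line-Detector Segmentation of Retinal Blood Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of blood vessels in color fundus photographs with a
    multi-scale oriented line detector. Small detection scales (line length
    L < 9) are applied to a locally contrast-enhanced image and large scales
    (L >= 9) to a globally enhanced image; per-scale responses are
    standardized, fused linearly with the inverted green channel, and
    thresholded into a binary vessel mask. Includes field-of-view handling,
    confusion-matrix evaluation (accuracy, true/false positive rate,
    F-measure), skeletonization, and a deterministic synthetic fundus-phantom
    generator with exact ground truth for download-free testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
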