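Package: stomabox
Title: Stomatal Phenotyping from Bounding-Box Detections in Leaf Imprint Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for bounding-box based stomatal phenotyping of
    grass leaf imprints. Generates synthetic wheat-like imprint micrographs with
    known ground truth (stomata arranged in horizontal files), reads and writes
    COCO object-detection JSON and a Labelbox-style export dialect, prepares
    detector training tiles (resize, pad, split with box coordinate remapping),
    provides oracle and template-matching stand-in detectors with non-maximum
    suppression, evaluates detections by IoU matching and mean average
    precision, converts detections to stomatal density, stomatal size and
    stomatal-file interval phenotypes with micrometre calibration and
    marginal-box exclusion, and runs the associated statistics: Welch's t test,
    random-subsampling power simulation and Pearson correlation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
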