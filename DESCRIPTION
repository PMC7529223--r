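Package: virtualstain
Title: Intensity Leveling and Beer-Lambert Virtual Staining of Fluorescence Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts two-channel 3D grayscale fluorescence volumes (a
    fluorescent analog of hematoxylin and eosin) into RGB images that mimic
    chromogenic H&E or DAB/hematoxylin staining. Implements a data-driven
    flat-field ("intensity leveling") correction built from local medians of
    down-sampled data cubes, a Beer-Lambert absorption model for digital
    staining, and a colorimetry pipeline (optical-density stain unmixing,
    Otsu segmentation, HSV statistics) to calibrate and validate rendered
    colors against standard histology. Includes a synthetic tissue-phantom
    generator so the full workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    rhdf5,
    png,
    tiff,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
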