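Package: MosaicROI
Title: ROI-Guided Mosaic Inputs and Localization Evaluation for Ultrasound
    Nodule Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building fixed-layout mosaic composite images (1x2 and
    2x2) from annotated grayscale ultrasound images with exact bounding-box
    bookkeeping, thresholding attention score maps at a top-k percent of
    pixels, scoring localization agreement between detected regions and
    reference regions of interest with IoU, IoR and IoD, and aggregating
    region-level classifications into image-level benign/malignant calls
    with confusion-matrix reporting. Includes a deterministic speckle
    phantom generator that renders hypoechoic nodules with known boxes and
    labels, and a rule-based reference detector, so the full
    detect-overlap-aggregate-evaluate pipeline is exercisable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification
RoxygenNote: 7.3.3
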