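Package: ColonyEdge
Title: Edge-Detection Segmentation and Measurement of Cell and Microbial
    Colonies in Digital Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated counting and measurement of cells and colonies
    (tumorspheres, bacterial plates, clonogenic assays) from 2-D digital
    images by an edge-detection pipeline: rolling-ball background
    subtraction, sharpening, Sobel edge detection, Gaussian smoothing,
    automatic binarization, morphological gap closing and hole filling,
    median-based outlier removal, distance-transform watershed splitting
    of touching objects, and particle measurement (area, perimeter,
    circularity, intensity) with size/shape filtering. Includes preset
    configurations for common assay types, batch processing of image
    folders, a synthetic scene generator with analytic ground truth, and
    an evaluation module that matches detected objects to reference
    measurements and quantifies agreement by least-squares regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: CellBasedAssays, Segmentation, Visualization
RoxygenNote: 7.3.3
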