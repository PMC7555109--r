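Package: musclemsi
Title: Multispectral Image Morphometry and Chemometrics for Muscle Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict biochemical (intramuscular fat, total and
    insoluble collagen) and microstructural (perimysium and endomysium
    geometry, muscle-fiber density) properties of meat from 19-band
    visible/near-infrared multispectral image cubes. The pipeline segments
    intramuscular connective tissue per band with contrast-limited adaptive
    histogram equalization, Prewitt edge detection and mathematical
    morphology, summarises the segmented objects with eight shape
    descriptors, assembles size-class frequency-histogram cubes, compresses
    them with univariate partial least squares, and fits grid-searched
    two-hidden-layer neural networks trained by Levenberg-Marquardt with an
    early-stopping validation split. A synthetic-scene simulator with exact
    mask-derived ground truth supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
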