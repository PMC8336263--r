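Package: xrfleaf
Title: Substructure Segmentation and Heritability of Metal Distribution
    in Plant Micro-XRF Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphological segmentation of micro X-ray fluorescence (micro-XRF)
    rosette scans into petiole, leaf margin, vasculature and interveinal tissue;
    quantification of spatial metal accumulation by the concentration quotient
    (the mean element intensity in a substructure divided by the whole-plant
    mean); and broad-sense heritability (repeatability) of these traits across
    accession panels via one-way random-effects models. Includes segmentation
    evaluation against manually labelled pixels, robustness tooling (random
    substructures, label-noise injection, parameter sensitivity sweeps) and a
    synthetic rosette generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    lme4,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
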