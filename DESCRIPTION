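Package: pollenid
Title: Pollen Grain Detection, Focal-Stack Projection and Open-Set
    Classification from Brightfield Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated monitoring of allergenic Urticaceae pollen
    in brightfield microscopy focal stacks. Detects individual pollen grains
    in calibrated multi-slice Z-stacks with circularity and size filters,
    removes out-of-focus slices, builds standard-deviation, minimum-intensity
    and extended-depth-of-field projections as the three channels of a
    fixed-size scale-preserving classifier input, and trains and evaluates an
    open-set three-class convolutional classifier (Urtica, Parietaria,
    Urtica membranacea) with stratified cross-validation, flip and brightness
    augmentation, weighted classification metrics, and a softmax identity
    threshold that rejects low-confidence grains as unknown. Includes a
    synthetic phantom generator producing labelled Z-stacks with ground
    truth, so the full pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
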