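Package: spherodens
Title: Density-Based Quantification of Tumor Spheroid Invasion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted quantification of multicellular tumor spheroid
    (MCTS) invasion assays from bright-field micrographs. Segments each image
    in three optimized passes (Otsu-thresholded core with shape plausibility
    checks, seeded watershed halo with a border stop criterion, Canny
    edge-density periphery), combines them into a tile-averaged binarization
    density map on the 0-255 scale, and integrates the map into a size measure
    that is normalized per sample to day 0. Includes a synthetic micrograph
    generator with exact ground truth and controllable illumination artifacts
    for validation, and a batch driver for whole-assay processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
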