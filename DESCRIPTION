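Package: oarseg
Title: Deep-Learning Autocontouring of Organs at Risk on Planning CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end automatic contouring of organs at risk (OARs) on
    radiotherapy planning CT. Reads DICOM CT series into calibrated
    Hounsfield-unit volumes, trains an independent 2D U-Net per organ with a
    combined Dice + binary cross-entropy loss, applies threshold /
    largest-component / axial-height post-processing, and writes
    DICOM-compliant RT Structure Set files. Includes surface-distance
    contour evaluation (Dice coefficient, mean surface distance,
    95th-percentile Hausdorff distance) with paired statistical comparison,
    and a deterministic synthetic head-phantom generator so the whole
    pipeline is testable at desk scale without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
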