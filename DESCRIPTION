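Package: endomosaic
Title: Synthetic Endothelial Mosaics and Calcein Fluorescence Viability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ground-truthed corneal endothelial cell mosaics
    (centroidal Voronoi geometry, surgical damage patterns, calcein-AM
    staining kinetics, fluorescence rendering) and quantifies graft
    viability from single-channel fluorescence images: 25x25-pixel patch
    photometry with signal-to-noise and viable/non-viable contrast
    statistics, ROC-calibrated threshold segmentation of the viable area,
    nuclear local-maxima cell counting with endothelial morphometry
    (density, hexagonality, coefficient of variation of cell area, dead
    fraction), and Bland-Altman agreement between paired density
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
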