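Package: pdquant
Title: Relational Quantification of Plasmodesmata and Callose in Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments two-channel surface images of plant tissue (cell-wall
    stain plus callose/plasmodesmata immunofluorescence) into a relational
    model of cells, wall segments and junction points, detects
    plasmodesmata-associated puncta as local intensity maxima, links each
    punctum to its parent wall and each wall to its adjacent cells, and
    quantifies callose and plasmodesmata per wall, per unit wall length and
    per cell. Also provides immunogold density normalization for electron
    microscopy counts, per-interface plasmodesmata count maps, bud-break
    timing heterogeneity statistics, and a synthetic tissue generator with
    exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    zip,
    png,
    deldir,
    viridisLite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
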