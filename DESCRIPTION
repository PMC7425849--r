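Package: specimen3d
Title: Automated Photogrammetry Post-Processing and Phenomics for Museum Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An open toolchain for turning turntable photogrammetry captures of
    natural-history specimens into measurement-ready 3D assets: color-chart
    exposure standardization and backdrop masking, ruler-based scale
    calibration, procedural mesh processing (voxel remeshing, quality-weighted
    decimation, topology cleanup, Taubin smoothing, canonical alignment, UV
    atlas generation), visibility-aware projective texture baking, and phenomic
    extraction (landmark morphometrics and area-weighted color clouds).
    Includes a synthetic-fixture generator (parametric specimens, scan-defect
    injection, posed turntable renders) so the whole pipeline is testable
    end to end without proprietary reconstruction software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    png,
    EBImage,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
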