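Package: aomosaic
Title: Morphometry of Retinal Cell Mosaics from Adaptive-Optics Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated morphometric characterization of retinal pigment
    epithelium (RPE) and cone photoreceptor mosaics imaged with adaptive-optics
    fundus cameras. Provides ocular magnification scaling from axial length,
    a fixation-relative retinal coordinate system with signed eccentricity,
    quality/vessel/mosaic masking, cell-centroid detection, masked Voronoi
    tessellation with per-cell area, perimeter and neighbor counts, grid-based
    aggregation with the associated filtering cascade, eccentricity profiles,
    density heatmaps, RPE-to-photoreceptor ratio matching, inter-rater
    agreement statistics (ICC(3,k)), and a synthetic-mosaic generator that
    emulates the acquisition geometry so that every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
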