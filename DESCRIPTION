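Package: fusemech
Title: Traction Microscopy and Compression Mechanics for Trophoblast Fusion
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the mechanics of trophoblast cell fusion in vitro.
    Recovers substrate deformations from fluorescent-bead time-lapse images by
    iterative multi-pass particle image velocimetry, reconstructs traction
    stress fields by regularized Fourier-transform traction cytometry on an
    elastic half-space, and decomposes stresses into radial and tangential
    components about the centroid of syncytial or mononucleated regions of
    interest. Also computes nuclear-count based fusion-efficiency statistics
    for monolayers, volume-normalized marker intensity for spheroids, and
    linear-elastic inversion of osmotically applied compressive pressure from
    spheroid shrinkage. A synthetic-data generator produces bead images,
    contraction movies, labeled fusion masks and spheroid tracks with known
    ground truth so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
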