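Package: gridspot
Title: Image Analysis for Grid-Structured High-Throughput Screens
Version: 0.1.0
Authors@R:
    person("gridspot", "maintainers", email = "gridspot@example.org",
           role = c("aut", "cre"))
Description: Automated image processing for grid-structured high-throughput
    screening platforms such as droplet microarrays and well plates. Provides
    grid geometry estimation (element segmentation, rotation estimation,
    robust lattice fitting, semi-automated completion), spot-wise instance
    segmentation via Euclidean distance maps and seeded watershed with
    region-feature extraction, three-channel live/dead viability fusion
    (Hoechst/Calcein/PI), colorimetric spot quantification with monotone
    calibration, assisted-annotation support (diversity-based sample
    ordering, classical pre-annotation, Dice and AJI+ inspection metrics),
    a deterministic synthetic scene generator with full ground truth, and a
    command-line pipeline runner with plain TIFF/PNG/CSV/JSON input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
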