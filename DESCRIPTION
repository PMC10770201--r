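Package: slnf
Title: Multi-Pinhole Gamma-Source Localization by Sentinel Lymph Node
    Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing point-like gamma sources (e.g. 99mTc-labelled
    sentinel lymph node tracer depots) from a single multi-pinhole collimator
    detector image. Implements the sparse binary system matrix relating a
    voxelized source volume to the detector plane, a Poisson detector-image
    simulator with collimator penetration and hot-background terms, the greedy
    correlation-maximizing SLNF (sentinel lymph node fingerprinting)
    reconstruction of a known number of sources with footprint masking, an
    A-optimal-design assessability score ranking candidate positions by
    expected localization difficulty, and an evaluation harness reporting
    median and third-quartile Euclidean localization errors over repeated
    acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
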