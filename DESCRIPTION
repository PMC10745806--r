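Package: axoquant
Title: Quantification of Axon Collateral Branching from Fluorescence Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 2D quantitative pipeline for axonal morphology in fluorescence
    microscopy. From a confocal stack and a user-traced axon path it produces
    straightened band images, binary collateral masks (thresholding,
    skeletonization, minimum-length filtering), spatial collateral-density
    profiles, scalar branching metrics with a dorsal/ventral regional split,
    and per-position group statistics with false-discovery-rate control.
    A seeded synthetic axon-phantom generator with machine-readable ground
    truth makes every pipeline stage verifiable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
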