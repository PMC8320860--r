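Package: clumptrack
Title: Tracking Cell Nuclei and Quantifying Direction Changes After Cell-Cell Contact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments two-channel fluorescence time-lapse movies of migrating
    cells (a nuclear channel and a microtubule channel), tracks nuclei across
    frames with a keyhole-style motion predictor, detects moments of cell-cell
    contact as multi-nucleus microtubule objects ("clumps"), encodes clump
    membership with positional base-1000 codes, and quantifies the signed
    change of direction of each cell before versus after contact against
    matched per-track control windows, with time-in-clump stratified paired
    statistics. Includes a seeded synthetic-movie generator with full ground
    truth so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
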