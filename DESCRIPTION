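Package: ctcscan
Title: Rare-Cell Detection and Spike-In Recovery Statistics for Tiled
    Immunofluorescence Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of cytokeratin-positive,
    CD45-negative nucleated cells (circulating-tumor-cell candidates) in
    tiled four-channel immunofluorescence slide images. Provides a
    synthetic slide simulator with ground truth, per-tile adaptive
    (median + k*MAD) thresholding and cytokeratin-primary segmentation,
    marker-correlation artifact rejection, rule-based Cell /
    Indeterminate / Not-a-Cell classification with a morphology gate,
    cross-tile deduplication and picklist generation for single-cell
    retrieval, and spike-in recovery statistics (per-line summaries,
    pooled regression, single-digit detection tallies, and a binomial
    spike-in simulator).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
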