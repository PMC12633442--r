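Package: safconn
Title: Histology-Guided Evaluation of Short-Range Prefrontal Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating tractography reconstructions of the short
    association (U-) fibers of the prefrontal cortex against the primate
    tract-tracing literature. Provides the 14-area / 5-partition prefrontal
    atlas and its 91 area-pair connection scheme, a packaged literature-derived
    histology reference and benchmark outcome table, streamline bundle I/O
    (MRtrix .tck) and voxel density maps, bundle-comparison metrics (Dice,
    density-weighted Dice, bundle adjacency), population-level classification
    of connections as robust/true positives, true negatives and false
    positives/negatives with confusion statistics, within- and between-subject
    reliability summaries, and a synthetic U-fiber phantom generator so that
    every pipeline stage is testable without diffusion imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
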