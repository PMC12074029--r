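Package: fcscreen
Title: Multi-Parameter Functional Connectivity Screening with EMG and
    Myelin Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state functional connectivity analysis for small-animal
    imaging cohorts: ROI-by-ROI Pearson correlation matrices, Fisher-z group
    averaging, edge-wise two-sample tests with false-discovery-rate or
    family-wise-error correction, Cohen's D effect-size matrices, a Node
    Modulation Index summarising per-region connectivity change, seed-based
    voxel-wise correlation and group t-maps, and correlation of screened edges
    with behavioural scores.  Companion electrophysiology and histology tools
    cover EMG amplitude and spectral analysis (RMS envelope, Welch power
    spectral density, band power, Morlet scalograms), g-ratio myelin
    morphometry with axon-diameter stratification, and skeleton-based fiber
    metrics (total length, branch points, node-degree density) from binary
    images.  A synthetic-cohort generator with planted, known-size effects
    supports calibration and power verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
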