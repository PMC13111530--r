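Package: correloscope
Title: Correlogram Shape Metrics for Multi-Unit Spike Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds auto- and cross-correlograms from multi-unit spike
    rasters over user-defined analysis regions and quantifies each
    correlogram's shape with three metrics: uniformity (chi-squared test
    against a flat histogram), peak count and peak times (local quadratic
    smoothing followed by prominence-based peak detection), and area left
    of zero (leader/follower firing order). Metrics are classified into
    categorical schemes whose per-region fractions, region-to-region
    transition probabilities, and combined-classification summaries track
    how network firing dynamics evolve across experimental treatments.
    Includes synthetic raster generators (Poisson populations, fixed-lag
    follower pairs, periodic population bursts, mid-recording regime
    switches) so every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
biocViews: Electrophysiology, TimeCourse, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
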