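Package: th17traj
Title: Trajectory, Clonotype and Spatial Colocalization Analysis of
    TH17 Cell Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the differentiation of IL-26-producing
    TH17 intermediates into IL-17A producers in inflamed skin.
    Implements graph-geodesic pseudotime from marker-defined root
    cells, stage-binned TCR clonotype tracking (Venn presence,
    cytokine-state flows, late-producer provenance), spatial
    transcriptomics spot gating with minimum-distance colocalization
    statistics and a two-sample Kolmogorov-Smirnov test, TGF-beta
    signature scoring, and a seeded synthetic-data generator that
    emulates the statistical structure of single-cell and spatial skin
    data for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
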