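Package: cardiophen
Title: Functional Phenotyping of Stem Cell-Derived Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of human pluripotent stem cell-derived
    cardiomyocyte function across imaging, electrophysiology, mechanics,
    metabolism and omics modalities. Extracts background-corrected calcium
    transients from fluorescence image stacks and computes per-beat kinetic
    metrics including the exponential relaxation constant tau; computes
    action-potential (APD50/APD90) and optical-wave (WD50/WD90) repolarization
    metrics; quantifies beat-rate variability with 95% confidence Poincare
    ellipses; converts micropost deflections to twitch force, velocity and
    power; decomposes Seahorse oxygen-consumption-rate assays into basal,
    ATP-linked, proton-leak, maximal and non-mitochondrial respiration;
    scores pathway-level net benefit of treatments by paired hypergeometric
    enrichment of up- and downregulated gene sets; filters single-cell
    RNA-seq matrices by standard quality-control thresholds; parses
    cardiolipin and acyl-carnitine lipid annotations with mTIC normalization
    and class summaries; and measures cell/mitochondrial morphometrics
    including circularity and two-channel colocalization. A seeded
    synthetic-data generator with literature-derived presets provides ground
    truth for parameter-recovery testing of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    minpack.lm,
    pracma,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
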