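Package: kamdecon
Title: Kinase Activity Deconvolution, Drug Synergy and Xenograft Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis stack for functional kinomics screens of targeted-therapy
    resistance: conversion of 384-well peptide-sensor luminescence plates to ATP
    consumption, internal-mean normalization and deconvolution of per-peptide
    phospho-catalytic activity into kinase activity signatures with differential
    statistics and hierarchical clustering; Bliss-independence combination-index
    scoring of two- and three-drug regimens anchored at GI50; zero-normalized
    standardized GLM effect sizes with FDR correction, per-time-point tests and
    waterfall regression summaries for multi-arm xenograft studies; 2^(-ddCt)
    relative expression with dual housekeeping controls; and seeded synthetic-data
    generators with known ground truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
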