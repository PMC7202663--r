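Package: tmejsig
Title: Deletion Junction Signatures and Mutation Rates for Mutation-Accumulation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the mutational footprint of polymerase
    theta-mediated end joining (TMEJ) in whole-genome-sequenced mutation
    accumulation (MA) lines. Provides strand-aware sequence primitives and a
    G-quadruplex motif scanner; readers for tab-separated variant tables and a
    minimal VCF subset with right-shifting ("maximal 5' conservation") indel
    normalisation; micro-homology heatmaps over deletion junctions with a
    composition-preserving shuffled null and per-cell chi-square tests;
    templated-insertion classification; breakpoint base-composition profiles
    with outlier flagging; per-generation mutation-rate estimation with exact
    Poisson intervals, rate ratios, and an exact Mann-Whitney U test; and a
    synthetic MA-line generator with ground-truth labels so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
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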