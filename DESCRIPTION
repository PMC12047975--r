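Package: ritox
Title: Systems Genetics of Drug-Induced Cardiotoxicity in Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("BXD", "Toolkit", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping drug-induced cardiotoxicity traits in
    two-founder recombinant inbred (RI) mouse panels such as the BXD family.
    Derives strain-level traits (Kaplan-Meier median survival, body-weight
    loss, echocardiographic deltas, 2Z+8 expression normalization) from
    per-animal records; runs single-marker Haley-Knott regression and
    EMMA-style mixed-model genome scans with permutation-based genome-wide
    thresholds and 2-LOD support intervals; prioritizes candidate genes in a
    QTL interval with a weighted multi-criteria score; estimates causal gene
    effects on disease outcomes by two-sample Mendelian randomization (Wald
    ratio and inverse-variance weighting); and performs hypergeometric
    over-representation analysis with Benjamini-Hochberg control. A
    synthetic-data generator with planted ground truth (RI genotype mosaics
    under sib-mating map expansion, additive QTL effects, linked
    eQTL/outcome summary statistics) makes every stage testable without
    access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
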