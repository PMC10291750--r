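Package: ctcpanel
Title: Marker-Panel Analysis and Simulation for Multiplexed CTC Gene
    Expression Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing highly multiplexed chemiluminescent
    gene-expression assays of circulating tumor cells (CTCs) captured from
    blood. Provides a calibrated simulator of spot-level array intensities
    (linear response to tumor-cell RNA, white-blood-cell background,
    detector saturation, lognormal replicate noise), background subtraction
    against no-template controls, titration linearity and limit-of-detection
    screening, three tiers of marker selection including CD45
    (PTPRC)-based deconfounding of leukocyte contamination, rank-correlation
    and Euclidean hierarchical clustering of sample cohorts, and a
    sequence-analysis module implementing multiplex primer/probe design
    constraints (amplicon GC windows, exon-junction spanning,
    nearest-neighbor melting temperatures, hairpin and cross-homology
    screens, universal primer tails).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
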