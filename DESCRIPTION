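Package: spliceMod
Title: Modulator-Dependent RBP Regulation of Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies (modulator, RNA-binding protein, skipped-exon event)
    triplets in which the expression level of a modulator gene changes the
    association between an RBP's expression and the inclusion level (PSI) of
    one of its bound exons. Provides readers for expression/PSI matrices,
    MISO-style event identifiers and eCLIP narrowPeak files; eligibility
    filters for genes and splicing events; an RBP-to-event target map built
    from enrichment-filtered, replicate-merged peaks intersected with
    flanked exon windows; a tertile-discretized interaction screen with
    Benjamini-Hochberg selection; a six-category conditional-correlation
    classifier of modulation mode; summary and clustering utilities; and a
    fully seeded synthetic-cohort generator so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
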