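Package: pgxpipe
Title: Proteogenomic Spectral-Count Analysis with Sample-Specific Protein Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated proteogenomic workflow for case-control shotgun
    proteomics studies with matched RNA-seq. Builds sample-specific protein
    reference databases by applying per-sample non-synonymous variants and
    novel splice events to transcript models, performs in-silico tryptic
    digestion and classifies identified peptides as reference or
    non-reference (single amino acid variant or novel isoform), quantifies
    by spectral counts with presence and group-exclusivity filters and
    upper-quartile normalisation, tests differential expression with a
    negative-binomial conditional exact test, tests differential usage of a
    novel exon with the Mann-Whitney U test, and computes gene-set
    over-representation and interaction-network connectivity statistics.
    Ships a synthetic-data generator emulating a two-group lung-tissue study
    design, including an in-frame novel-exon scenario, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
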