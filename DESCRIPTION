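Package: splicescape
Title: Alternative Splicing, Novel Transcript Discovery and Expression
    Statistics for Two-Condition RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two pooled RNA-seq libraries at the
    transcript level: discovery and evidence-based filtering of novel
    multi-exonic transcribed units, classification of isoform pairs into
    the six simple alternative-splicing event categories (exon skipping,
    alternative 5'/3' splice site, intron retention, mutually exclusive
    exons, alternative last exon), Jensen-Shannon differential isoform
    usage testing by multinomial bootstrap, FPKM and upper-quartile
    normalization, gene-length-bias-corrected category enrichment via the
    Wallenius noncentral hypergeometric distribution, and geNorm and
    delta-delta-Ct qPCR validation statistics.  A seeded synthetic-data
    generator with planted ground truth supports end-to-end testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
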