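Package: tscs
Title: Transcript SNV Discrimination from Complementary Short- and Long-Read RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a true/false transcript single-nucleotide variant (SNV)
    truth set by combining deep short-read RNA-seq calls with uniform,
    complete-coverage long-read evidence, trains a classifier on 12 VCF-level
    and 9 exon-context features with AUROC-based model selection over five
    algorithm families, and partitions confirmed transcript SNVs into
    genome-derived (g-tSNV) and editing-derived (e-tSNV) classes with
    substitution-spectrum, genomic-region, and protein-consequence
    characterization. A seeded synthetic dual-platform data generator
    reproduces the platform contrasts (depth, exon coverage fraction,
    per-exon depth uniformity, per-site allele consistency) so the whole
    workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
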