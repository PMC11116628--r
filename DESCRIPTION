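Package: delclust
Title: Deletion Structural Variant Calling from Long-Read Alignments by
    Two-Layer Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects deletion structural variants (>= 50 bp) from long-read
    alignments. Deletion signatures are extracted from CIGAR 'D' runs
    (intra-read evidence) and from split alignments of one read to two
    non-adjacent same-strand loci (inter-read evidence), merged within reads,
    clustered in two layers (a size-stratified first layer using sliding
    windows for large events and coverage peaks for small ones, then
    agglomerative clustering on deletion length to separate heterozygous
    alleles of different lengths), filtered by read support, and written as
    VCF. Includes a deterministic synthetic-alignment generator and a
    Truvari-style precision/recall evaluator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rsamtools,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
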