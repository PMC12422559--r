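Package: chromalign
Title: Chromatin Domain Annotation by Aligning Hi-C and Epigenomic Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates chromatin domain types at fixed genomic bin resolution
    by integrating Hi-C contact maps with multi-track epigenomic signals.
    Hi-C contacts are embedded with the LINE graph-embedding algorithm, a
    structural and a functional encoder are trained jointly with a
    bidirectional InfoNCE contrastive loss so that the two modalities agree
    per bin, and the concatenated embeddings are partitioned into K domain
    types with K-means. Includes an evaluation battery (variance explained,
    loop observed/expected ratios, fold enrichment, adjusted Rand index,
    overlap matrices, coverage and segment statistics), a planted-domain
    genome simulator for end-to-end testing, and readers and writers for the
    common text formats (contact matrix TSV, bedGraph, BEDPE, BED,
    chrom.sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
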