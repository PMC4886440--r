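Package: viticre
Title: Berry-Size Transcriptome Clustering and Promoter Cis-Regulatory
    Element Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links differential gene expression between small and large
    grape berries to regulatory structure. Provides FPKM computation and
    expression filtering, per-stage differential-expression selection and
    Venn partitioning, k-means clustering of log2 fold-change profiles
    with Spearman rank correlation as the similarity metric, hierarchical
    MapMan-BIN overrepresentation (Fisher's exact test with Bonferroni
    correction), and promoter cis-regulatory-element enrichment by IUPAC
    degenerate motif scanning with hypergeometric tests and
    Benjamini-Hochberg false-discovery-rate control. A synthetic-data
    generator emulates the study design (two berry size classes, four
    developmental stages, three replicates) with planted cluster, BIN,
    and motif structure so every stage of the pipeline can be validated
    against a recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    mclust,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
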