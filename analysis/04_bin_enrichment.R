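#!/usr/bin/env Rscript
# MapMan-BIN overrepresentation per k-means cluster: one-sided Fisher
# exact test of each prefix-expanded BIN against the expressed background,
# Bonferroni-corrected within each cluster, called at adjusted p < 0.05.

suppressMessages(library(viticre))

clusters_tab <- read.delim("results/clusters.tsv")
labels <- setNames(clusters_tab$cluster, clusters_tab$gene)
bins <- read_bin_annotation("results/data/bins.tsv")
filt <- read.delim("results/filter_report.tsv")
background <- filt$gene[filt$retained]

res <- enrich_bins(labels, bins, background = background, alpha = 0.05)
write_enrichment_table(res, "results/bin_enrichment.tsv")

sig <- res[res$enriched, ]
message(nrow(sig), " enriched (cluster, BIN) pairs at Bonferroni-adjusted p < 0.05")
if (nrow(sig)) {
  print(sig[, c("set_id", "term", "k", "n", "K", "N", "p_adjusted")],
        row.names = FALSE)
}
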