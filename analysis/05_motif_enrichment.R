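#!/usr/bin/env Rscript
# Promoter CRE analysis per k-means cluster: extract 1 kb promoters from
# the genome + annotation, scan the packaged PLACE/PBM motif library on
# both strands, and test per-cluster overrepresentation with the
# hypergeometric tail, BH-FDR within cluster, called at FDR < 0.01.

suppressMessages(library(viticre))

genome <- read_genome_fasta("results/data/genome.fasta")
models <- read_gene_models("results/data/genes.gff3")
clusters_tab <- read.delim("results/clusters.tsv")
labels <- setNames(clusters_tab$cluster, clusters_tab$gene)
lib <- packaged_motif_library()

promoters <- extract_promoters(genome, models, length = 1000)
message(nrow(promoters), " promoters extracted (",
        sum(promoters$clipped), " clipped)")

res <- enrich_motifs(labels, promoters, lib, strands = "both",
                     fdr_threshold = 0.01)
write_enrichment_table(res, "results/motif_enrichment.tsv")

pres <- motif_presence_matrix(promoters, lib)
write.table(data.frame(gene = rownames(pres), pres, check.names = FALSE),
            "results/motif_presence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- res[res$enriched, ]
message(nrow(sig), " enriched (cluster, motif) pairs at FDR < 0.01")
if (nrow(sig)) {
  print(sig[, c("set_id", "term", "pattern", "family", "k", "n", "K", "N",
                "p_adjusted")], row.names = FALSE)
}
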