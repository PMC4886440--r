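#!/usr/bin/env Rscript
# Simulate the study dataset: a one-contig genome with 2000 genes, 1 kb
# promoters carrying planted CRE instances, negative-binomial counts for
# 2 berry size classes x 4 stages (47/74/103/121 DAA) x 3 replicates with
# planted DE/cluster structure, and MapMan-style BIN annotations with
# planted per-cluster enrichment. Ground truth is written alongside.

suppressMessages(library(viticre))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- default_run_config(seed = 1L)

sim_cfg <- sim_config(
  n_genes = cfg$n_genes, promoter_length = cfg$promoter_length,
  n_clusters = cfg$n_clusters, de_fraction = cfg$de_fraction,
  profile_noise_sd = cfg$profile_noise_sd, nb_dispersion = cfg$nb_dispersion,
  motif_plant_rules = cfg$motif_rules, bin_plant_rules = cfg$bin_rules,
  seed = cfg$seed
)

gen <- generate_genome(sim_cfg)
cts <- simulate_counts(sim_cfg, gen$models)
promoters <- extract_promoters(gen$genome, gen$models, cfg$promoter_length)
lib <- packaged_motif_library()
planted <- plant_motifs(promoters, lib, cfg$motif_rules,
                        cts$truth$cluster_of_gene, seed = cfg$seed + 2L)
genome <- patch_genome_with_promoters(gen$genome, gen$models,
                                      planted$promoters, cfg$promoter_length)
bins <- assign_bins(gen$models$gene_id, default_bin_catalog(), cfg$bin_rules,
                    cts$truth$cluster_of_gene,
                    background_rate = cfg$bin_background_rate,
                    seed = cfg$seed + 3L)

write_genome_fasta(genome, file.path(outdir, "genome.fasta"))
write_gene_models(gen$models, file.path(outdir, "genes.gff3"))
write_count_matrix(cts$counts, file.path(outdir, "counts.tsv"))
write_de_table(cts$de_table, file.path(outdir, "de_table.tsv"))
write_bin_annotation(bins, file.path(outdir, "bins.tsv"))
truth <- data.frame(gene = names(cts$truth$cluster_of_gene),
                    cluster = unname(cts$truth$cluster_of_gene))
write.table(truth, file.path(outdir, "truth_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = ".")

n_de <- sum(!is.na(cts$truth$cluster_of_gene))
message("simulated ", nrow(gen$models), " genes on a ",
        round(sim_cfg$contig_length / 1e6, 1), " Mb contig; ",
        n_de, " planted DE genes across ", cfg$n_clusters, " archetypes; ",
        nrow(planted$sites), " planted motif instances")
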