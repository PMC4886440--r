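#!/usr/bin/env Rscript
# Expression analysis: FPKM from counts, the low-expression filter
# (discard iff max FPKM < 0.5 AND max count < 5), per-stage DE selection
# at FDR < 0.05, the 4-way Venn partition of DE sets, and the DE-gene
# log2 fold-change (small/large) matrix that feeds the clustering step.

suppressMessages(library(viticre))

data_dir <- "results/data"
outdir <- "results"
counts <- read_count_matrix(file.path(data_dir, "counts.tsv"))
models <- read_gene_models(file.path(data_dir, "genes.gff3"))
de_tab <- read_de_table(file.path(data_dir, "de_table.tsv"))

fpkm <- compute_fpkm(counts, models)
filt <- filter_expressed(fpkm, counts, fpkm_min = 0.5, count_min = 5)
message(length(filt$retained), " of ", nrow(counts),
        " genes pass the expression filter")
write.table(filt$report, file.path(outdir, "filter_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

de_tab <- de_tab[de_tab$gene %in% filt$retained, ]
de <- select_de_genes(de_tab, alpha = 0.05)
per_stage <- vapply(de$per_stage, length, integer(1))
message("DE genes per stage (47/74/103/121 DAA): ",
        paste(per_stage, collapse = "/"),
        "; union ", length(de$union))

venn <- venn_partition(de$per_stage)
write.table(venn, file.path(outdir, "venn_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fc <- build_foldchange_matrix(de_tab, de$union)
write.table(data.frame(gene = rownames(fc), fc, check.names = FALSE),
            file.path(outdir, "foldchange_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("fold-change matrix: ", nrow(fc), " genes x ", ncol(fc), " stages")
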