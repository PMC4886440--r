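# viticre

Transcriptome-to-regulation analysis for berries of different sizes.

In wine grapes, berry size is believed to shape quality: small berries
have a higher skin-to-flesh ratio and different ripening kinetics than
large ones. Comparing the skin transcriptomes of small and large berries
across development (47, 74, 103 and 121 days after anthesis, two size
classes, three biological replicates) yields, per stage, sets of
differentially expressed (DE) genes and their log2 fold changes
(small/large). `viticre` implements the downstream analysis that links
those DE genes to regulatory structure, and a fully seeded synthetic-data
generator that makes every step testable against planted ground truth.

## What the package computes

1. **Expression.** FPKM = count / (exonic kb) / (library size in
   millions); genes are discarded iff max FPKM < 0.5 **and** max count
   < 5 across samples; per-stage DE sets are selected at FDR < 0.05 and
   partitioned into a 4-way Venn; DE genes form a genes × 4 matrix of
   log2FC (small/large) values.
2. **Clustering.** k-means on log2FC profiles with Spearman rank
   correlation as the similarity metric (k = 8, 1000-iteration cap,
   seeded restarts). Recovery of planted structure is scored with the
   adjusted Rand index (ARI).
3. **Functional enrichment.** Hierarchical MapMan-BIN
   overrepresentation per cluster: one-sided Fisher exact test
   (hypergeometric tail) of each prefix-expanded BIN against the
   expressed background, Bonferroni-corrected within the cluster,
   called at adjusted p < 0.05.
4. **Promoter cis-regulatory elements.** 1 kb promoters (upstream of
   the TSS, on the gene's strand) are extracted from FASTA + GFF3 and
   scanned on both strands with a packaged library of 22 degenerate
   IUPAC motifs (PLACE/PBM: ABRE/bZIP, bHLH, AP2/ERF, MYB, NAC,
   MADS-box, ARF, WRKY, TCP, E2F, light-response). Per cluster and
   motif, with k of n cluster promoters and K of N background promoters
   containing the motif, enrichment is the hypergeometric upper tail
   P(X ≥ k), BH-FDR-corrected within the cluster, called at FDR < 0.01.

The simulator plants all of this signal — archetype log2FC profiles,
per-cluster BIN enrichment, motif instances at controlled target and
background probabilities, negative-binomial counts
(variance = μ + φμ²) — and records the truth, so the pipeline's power
and error control are measurable.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default synthetic dataset (2000 genes, 6 Mb contig, 300 planted DE
genes in 8 archetypes, 24 samples):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_expression.R
Rscript analysis/03_clustering.R
Rscript analysis/04_bin_enrichment.R
Rscript analysis/05_motif_enrichment.R
```

which prints, step by step:

```
simulated 2000 genes on a 6 Mb contig; 300 planted DE genes across 8 archetypes; 685 planted motif instances
1994 of 2000 genes pass the expression filter
DE genes per stage (47/74/103/121 DAA): 149/149/149/149; union 298
adjusted Rand index vs planted truth: 0.977 over 298 genes
4 enriched (cluster, BIN) pairs at Bonferroni-adjusted p < 0.05
 set_id term  k  n   K    N   p_adjusted
      2   17 10 38 142 1994 0.0038969246
      2 17.1  6 38  50 1994 0.0052110001
      6   10 11 38 143 1994 0.0010623063
      6 10.6  8 38  41 1994 0.0000131869
4 enriched (cluster, motif) pairs at FDR < 0.01
 set_id            term  pattern    family  k  n   K    N   p_adjusted
      3     CACGTGMOTIF   CACGTG bHLH/bZIP 24 39 641 2000 2.744585e-03
      3          IRO2OS  CACGTGG bHLH/bZIP 16 39 363 2000 7.095908e-03
      4 ABREATCONSENSUS YACGTGGC ABRE/bZIP 15 37 270 2000 7.860594e-04
      7           TCP15 GGNCCCAC       TCP 20 36 405 2000 5.585709e-05
```

Reading the tables: six genes fell below both filter thresholds; each
planted archetype is significant at two stages, so per-stage DE sets
overlap pairwise in the Venn; k-means recovers the planted partition
almost perfectly (ARI 0.977); the hormone-metabolism BIN 17 and its
abscisic-acid child 17.1 are over-represented in one cluster and the
cell-wall BIN 10 / degradation child 10.6 in another (k of n cluster
genes vs K of N background genes annotated); and planted ABRE/bZIP, bHLH
and TCP promoter elements surface in the clusters where they were
implanted. The same computation is available as a single call,
`run_pipeline(default_run_config(seed = 1), "outdir")`, which also
writes a manifest with per-file checksums for byte-level
reproducibility.

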