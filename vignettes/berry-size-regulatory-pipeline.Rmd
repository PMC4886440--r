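---
title: "From berry-size fold changes to regulatory structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From berry-size fold changes to regulatory structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`viticre` analyses differential gene expression between small and large
grape berries across four developmental stages (47, 74, 103, 121 days
after anthesis, DAA) and connects it to regulatory structure at two
levels: functional categories (MapMan BINs) and promoter cis-regulatory
elements (CREs). This vignette explains the models and procedures, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where the design was genuinely
open.

## The analysis model

### Expression units and filtering

Transcript abundance is expressed as FPKM,

$$\mathrm{FPKM}_{gs} = \frac{c_{gs}}{(\ell_g/10^3)\,(L_s/10^6)},$$

with $c_{gs}$ the fragments assigned to gene $g$ in sample $s$,
$\ell_g$ the exonic length in bp, and $L_s$ the per-sample assigned-
fragment total. Genes are discarded iff their maximum FPKM across all
24 samples is below 0.5 **and** their maximum count is below 5. The
conjunction is deliberate: of the two readings of the filter sentence
("FPKM < 0.5 and counts < 5 discarded"), the AND rule is the
conservative one — it discards the fewest genes, only those failing both
evidence types everywhere. Both the AND/OR switch and the aggregation
(max vs mean across samples) are exposed as options in
`filter_expressed()`, because neither is derivable from the verbal rule.
Thresholds are strict (`<`), so a gene sitting exactly at FPKM 0.5 is
retained.

### DE selection and the fold-change matrix

Differential expression is consumed, not estimated: the pipeline takes a
table of (gene, stage, log2FC, FDR) rows, either produced externally by
a count-based test or emitted by the simulator with a planted
significance flag. A gene is DE at a stage iff FDR < 0.05 (strict). The
union of the four per-stage sets defines the rows of the genes × 4
log2FC matrix (stage order 47, 74, 103, 121 DAA; log2FC is
small/large, so positive values mean higher expression in small
berries). Keeping the DE test external means the package makes no claim
about dispersion estimation; its contract starts at the DE table.

### Clustering under rank correlation

Profiles are clustered by k-means with Spearman rank correlation as the
similarity metric: assignment maximises the rank correlation between a
gene's profile and each centroid; the update step takes the arithmetic
mean of member profiles. Defaults are k = 8, a 1000-iteration cap, and
10 restarts seeded from the master seed (restarts are our addition —
a plain similarity-k-means is sensitive to initialisation, and the
best-objective restart is reported).

Three numerical points deserve care:

* **Mixed objective.** Because the metric is rank-based but centroids
  are arithmetic means, the full loop is a heuristic without a global
  monotone convergence guarantee. The loop therefore stops on
  assignment stability or the iteration cap. What *is* guaranteed — and
  asserted on every iteration — is that the assignment step with fixed
  centroids never decreases the objective (it is an argmax). An option
  switches to Pearson on the raw log2FC values, which restores a more
  conventional geometry.
* **Degenerate profiles.** A constant profile has no ranks; its
  similarity is defined as 0 (with a warning) rather than NA, so such
  genes attach to whichever cluster wins ties (lowest id) instead of
  poisoning the iteration.
* **Empty clusters** are reseeded with the gene worst-fit to its
  current centroid, so exactly k clusters always come back.

Length-4 profiles make Spearman coarse: there are only 24 tie-free rank
orderings, so at most 24 rank-distinguishable shapes exist. This is a
real limitation of rank similarity at four stages, not of the
implementation, and it drives a fixture choice below.

### Overrepresentation statistics

Both enrichment layers reduce to the same contingency question: a
cluster contains $k$ of $n$ genes with a property that $K$ of $N$
background genes have. The enrichment p-value is the hypergeometric
upper tail

$$p = P(X \ge k) = \sum_{j=k}^{\min(n,K)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

computed via the log-space stable tail routine, and identical to the
one-sided (greater) Fisher exact test — an identity the test suite
asserts to $10^{-12}$ against exhaustive enumeration for all
$N \le 25$.

Multiple testing follows the table structure it feeds: BIN tests are
Bonferroni-corrected *within each cluster* over the terms actually
tested there (terms with zero cluster hits are skipped before
correction, since only present terms are reported); motif tests are
BH-FDR-corrected *within each cluster* over the whole motif library.
Thresholds: adjusted p < 0.05 for BINs, FDR < 0.01 for motifs.
Per-cluster correction families match how the result tables are
organised; a global family is a one-line change for a user who wants
it.

BIN membership is prefix-closed: a gene annotated `16.8`
(secondary metabolism.flavonoids) also counts for `16`. The background
for BIN tests is the set of expressed, annotated genes after the
expression filter; for motif tests it is all genes with extractable
promoters ("in the genome"), with an option to restrict to the
expressed set.

### Promoters and motif scanning

The promoter of a gene is the 1 kb immediately upstream of its TSS on
the gene's own strand: for a plus-strand TSS at $t$ (1-based) the
genomic interval $[\max(1, t-1000),\, t-1]$ as-is; for a minus-strand
TSS the interval $[t+1,\, \min(L, t+1000)]$ reverse-complemented.
Promoters truncated by a contig edge are *retained* and flagged rather
than silently dropped — excluding them would change $N$ invisibly; the
behaviour is switchable and logged. Genes with zero upstream sequence
are excluded with a message.

Motifs are degenerate IUPAC strings (R = A/G, Y = C/T, …, N = any).
The scanner translates each pattern into a character-class regular
expression; `both`-strand mode (the default — PLACE-style elements are
conventionally strand-agnostic) additionally scans the
reverse-complemented pattern on the forward sequence, which is
equivalent to scanning the reverse strand. Two conservative rules: an
N in the *sequence* (assembly gap) satisfies only the motif letter N,
so gaps never inflate $K$; and counting is presence/absence per
promoter — multiple occurrences count once, matching how
"promoters containing the element" tables are defined. The scanner is
validated against a brute-force oracle that expands every degenerate
pattern into all its concrete strings and tests plain substring
containment.

## The synthetic-data generator

The generator emulates the study geometry — 2 size classes × 4 stages ×
3 replicates = 24 samples — with planted, recorded truth at every
level:

* **Genome and annotation.** One contig of i.i.d. uniform A/C/G/T
  (GC configurable), genes on both strands placed in fixed-pitch slots
  with jitter such that every gene keeps ≥ 1 promoter length clear on
  both sides. Uniform background makes chance match rates closed-form
  ($1 - (1 - m\,4^{-w}\cdot 2)^{L-w+1}$ for a motif with $m$ concrete
  expansions of width $w$, both strands), which the tests exploit.
  Infeasible packing is an error, not a silent truncation.
* **Counts.** Negative binomial with $\mathrm{Var} = \mu + \phi\mu^2$
  (φ = 0.05 by default, a typical biological-replicate dispersion;
  φ = 0 degenerates to Poisson). Baseline means span
  $10^{-1}$–$10^{3.5}$ so the expression filter has genuine work.
  A `de_fraction` of 0.15 of genes (the rough DE share of an expressed
  transcriptome in this contrast) receives an archetype log2FC profile;
  at each stage the small/large mean ratio is $2^{\mathrm{log2FC}}$,
  split symmetrically around the baseline. Library sizes are left
  equal-by-construction so normalisation choice is inert.
* **Archetypes.** Eight 4-stage shapes scaled to ±1.5 log2 units,
  chosen to have *pairwise distinct rank orderings* — under Spearman
  similarity two shapes sharing a rank pattern are indistinguishable by
  construction, so rank-distinctness is the precondition for planted
  clusters to be recoverable at all. Profile noise is Gaussian,
  sd 0.3 log2 units per stage.
* **Truth DE flags.** A planted-DE gene is flagged significant at a
  stage iff its |archetype log2FC| ≥ 1 there (flagged rows carry
  fdr $10^{-4}$, others 0.5). With the default archetypes each DE gene
  is significant at two of four stages, producing stage-specific DE
  sets and a structured Venn — the flag stands in deterministically for
  an external DE test's FDR column.
* **BINs and motifs.** Each catalog BIN annotates genes at a 2 %
  background rate; planted rules multiply that rate (factor 10 by
  default) inside a target cluster. Motif instances — random concrete
  expansions of the IUPAC pattern, random strand and offset, never
  overwriting one another — are implanted with probability 0.6 in
  target-cluster promoters and 0.08 elsewhere, then written back into
  the genome FASTA so the whole pipeline can start from files.

What the generator does **not** emulate: read-level data (FASTQ, GC or
positional bias, mapping ambiguity), multi-isoform structure, real
promoter base composition (CpG/TATA structure, repeats), correlated
gene–gene expression, and library-size variation. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its stated model — not that the model captures every
property of real grape RNA-seq.

## Problem sizes and calibration checks

The test suite runs everything at sizes chosen for completeness per
minute: the scanner oracle over the full 22-motif library × 1000 random
60-nt sequences; hypergeometric enumeration for all valid counts with
N ≤ 25; motif power at the canonical planted setting (150-gene cluster,
60 % vs 8 % planting, 2000 × 1 kb promoters, 50 replicates) with a
1000-replicate null calibration; BIN recovery (factor 10, 200
replicates) with a 1000-replicate family-wise-error null; cluster
recovery (8 archetypes × 50 genes, noise 0.3, 20 seeds, median ARI
≥ 0.8); and byte-identity of two complete 600-gene pipeline runs under
one seed. The acceptance script runs the full 2000-gene pipeline.

One honest caveat the defaults expose: at the default study scale the
DE union (~300 genes) splits into clusters of ~37, and for motifs whose
chance presence in uniform 1 kb promoters is already high (a 6-mer
literal sits near 38 %), per-cluster power at FDR < 0.01 is marginal —
across seeds one of the four planted motifs (and occasionally a planted
BIN) lands just above threshold. This mirrors the real analytical
situation (short degenerate elements are weakly informative per
promoter) and is reported as-is rather than tuned away; the dedicated
power tests use the larger 150-gene cluster setting where recovery is
essentially certain.

## Known limitations

* Spearman on 4 points is coarse (ties everywhere); Pearson mode exists
  but changes the clustering question slightly.
* Presence/absence counting ignores motif multiplicity and position;
  positional weight matrices and occurrence-level statistics are out of
  scope.
* The DE table is trusted as given; no count-based test is performed
  in-package.
* The Bonferroni/BH families are per-cluster by design; users testing
  many clusters may prefer the global-family option.
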