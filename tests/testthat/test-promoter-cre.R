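test_that("promoter extraction follows the coordinate contract on both strands", {
  fx <- write_tiny_genome()
  genome <- read_genome_fasta(fx$fasta)
  models <- data.frame(
    gene_id = c("plus", "minus", "edge"),
    contig = "c1",
    start = c(1500L, 100L, 300L),
    end = c(2500L, 200L, 400L),
    strand = c("+", "-", "+"),
    exonic_length = c(1001L, 101L, 101L),
    stringsAsFactors = FALSE
  )
  pr <- extract_promoters(genome, models, length = 1000)
  seq <- fx$seq
  # + strand, TSS 1500: bases 500..1499 as-is
  expect_equal(pr$sequence[pr$gene_id == "plus"], substr(seq, 500, 1499))
  expect_equal(pr$length[pr$gene_id == "plus"], 1000L)
  expect_false(pr$clipped[pr$gene_id == "plus"])
  # - strand, TSS (gene end) 200: revcomp of bases 201..1200
  expect_equal(pr$sequence[pr$gene_id == "minus"],
               oracle_revcomp(substr(seq, 201, 1200)))
  # + strand, TSS 300: clipped to bases 1..299
  expect_equal(pr$sequence[pr$gene_id == "edge"], substr(seq, 1, 299))
  expect_equal(pr$length[pr$gene_id == "edge"], 299L)
  expect_true(pr$clipped[pr$gene_id == "edge"])
})

test_that("genes with no upstream sequence are excluded, bad contigs error", {
  genome <- c(c1 = "ACGTACGTAC")
  m1 <- data.frame(gene_id = "g1", contig = "c1", start = 1L, end = 5L,
                   strand = "+", exonic_length = 5L)
  expect_message(pr <- extract_promoters(genome, m1, 10), "excluding")
  expect_equal(nrow(pr), 0L)
  m2 <- data.frame(gene_id = "g1", contig = "cX", start = 2L, end = 5L,
                   strand = "+", exonic_length = 4L)
  expect_error(extract_promoters(genome, m2), class = "viticre_coordinate_error")
})

test_that("reverse complement is the standard involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")      # palindrome
  expect_equal(reverse_complement("GTGGC"), "GCCAC")
  expect_equal(reverse_complement("AN"), "NT")
  withr::with_seed(7, x <- rand_test_seqs(20, 35, seed = 7))
  expect_equal(reverse_complement(reverse_complement(x)), x)
  expect_error(reverse_complement("ACGU"), class = "viticre_alphabet_error")
})

test_that("IUPAC matching expands degeneracy codes correctly", {
  expect_true(iupac_match("TTCACGTGAA", "CACGTG"))
  expect_true(iupac_match("AACGCGC", "MACGYGB"))       # M->A, Y->C, B->C
  expect_true(iupac_match("CAATATTAAG", "CWWWWWWWWG"))
  expect_false(iupac_match("CAATACTAAG", "CWWWWWWWWG", strands = "forward"))
  # an N in the sequence satisfies only the motif letter N
  expect_false(iupac_match("CANGTG", "CACGTG"))
  expect_true(iupac_match("CANGTG", "CANGTG"))
})

test_that("matching both strands equals matching the reverse-complemented sequence", {
  lib <- packaged_motif_library()
  seqs <- rand_test_seqs(200, 60, seed = 31)
  for (p in lib$pattern) {
    both <- iupac_match(seqs, p, "both")
    manual <- iupac_match(seqs, p, "forward") |
      iupac_match(oracle_revcomp(seqs), p, "forward")
    expect_identical(both, manual)
  }
})

test_that("the scanner agrees with brute-force pattern expansion", {
  lib <- packaged_motif_library()
  seqs <- rand_test_seqs(150, 60, seed = 77)
  for (p in lib$pattern) {
    expect_identical(iupac_match(seqs, p, "both"),
                     oracle_iupac_match(seqs, p, "both"))
    expect_identical(iupac_match(seqs, p, "forward"),
                     oracle_iupac_match(seqs, p, "forward"))
  }
})

test_that("promoter counting is presence/absence", {
  pr <- data.frame(
    gene_id = c("a", "b", "c"),
    sequence = c("TTCACGTGTTCACGTGTT",  # two occurrences, counts once
                 "GGGCACGTGAAA",
                 "TTTTTTTTTTTT"),
    length = c(18L, 12L, 12L), clipped = FALSE
  )
  expect_equal(count_promoters_with_motif(pr, "CACGTG"), 2L)
  expect_equal(count_promoters_with_motif(pr, "GAGTGAG"), 0L)
})

test_that("empirical chance match rate approaches the closed form", {
  # literal 6-mer on both strands of uniform 1 kb sequence:
  # per-window hit probability 2 * 4^-6 over L - w + 1 windows
  n <- 1500
  seqs <- rand_test_seqs(n, 1000, seed = 55)
  pr <- data.frame(gene_id = paste0("g", 1:n), sequence = seqs,
                   length = 1000L, clipped = FALSE)
  emp <- count_promoters_with_motif(pr, "GAGTGA") / n
  expected <- 1 - (1 - 2 * 4^-6)^995
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(emp - expected), 4 * se + 0.01)  # first-order form ignores overlap
})

test_that("motif enrichment flags a strongly planted motif and handles K = 0", {
  n <- 600
  seqs <- rand_test_seqs(n, 300, seed = 10)
  pr <- data.frame(gene_id = paste0("g", 1:n), sequence = seqs,
                   length = 300L, clipped = FALSE)
  lib <- packaged_motif_library()
  clusters <- setNames(c(rep(1L, 80), rep(NA_integer_, n - 80)), pr$gene_id)
  rules <- data.frame(motif = "ABREATCONSENSUS", cluster = 1L,
                      p_target = 0.7, p_background = 0.02)
  planted <- plant_motifs(pr, lib, rules, clusters, seed = 3)
  res <- enrich_motifs(list("1" = pr$gene_id[1:80]), planted$promoters, lib)
  row <- res[res$set_id == "1" & res$term == "ABREATCONSENSUS", ]
  expect_true(row$enriched)
  expect_true(row$k <= row$K && row$k <= row$n)
  expect_true(all(res$k <= res$K & res$k <= res$n))
  # a motif absent from the background can never be flagged
  lib0 <- rbind(lib, data.frame(name = "IMPOSSIBLE", pattern = "GCGCGCGCGCGCGCGC",
                                family = "none", source = "text"))
  res0 <- enrich_motifs(list("1" = pr$gene_id[1:80]), planted$promoters, lib0)
  r0 <- res0[res0$term == "IMPOSSIBLE", ]
  expect_equal(r0$K, 0L)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p_raw, 1)
  expect_false(r0$enriched)
})

test_that("enrichment output is deterministic and clusters without promoters are skipped", {
  n <- 100
  pr <- data.frame(gene_id = paste0("g", 1:n),
                   sequence = rand_test_seqs(n, 200, seed = 2),
                   length = 200L, clipped = FALSE)
  lib <- packaged_motif_library()
  sets <- list("1" = paste0("g", 1:30), "2" = paste0("g", 31:60))
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.tsv"); f2 <- file.path(dir, "b.tsv")
  write_enrichment_table(enrich_motifs(sets, pr, lib), f1)
  write_enrichment_table(enrich_motifs(sets, pr, lib), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_warning(
    res <- suppressMessages(enrich_motifs(list(bad = c("nope1", "nope2")), pr, lib)),
    "skipped"
  )
  expect_equal(nrow(res), 0L)
})

test_that("patched genomes reproduce planted promoters on re-extraction", {
  cfg <- sim_config(n_genes = 30L, seed = 12)
  gen <- generate_genome(cfg)
  pr <- extract_promoters(gen$genome, gen$models)
  lib <- packaged_motif_library()
  clusters <- setNames(rep(1L, 30), gen$models$gene_id)
  rules <- data.frame(motif = "CARGCW8GAT", cluster = 1L,
                      p_target = 1, p_background = 0)
  planted <- plant_motifs(pr, lib, rules, clusters, seed = 5)
  patched <- patch_genome_with_promoters(gen$genome, gen$models, planted$promoters)
  again <- extract_promoters(patched, gen$models)
  expect_identical(again$sequence, planted$promoters$sequence)
  # certainty planting: every promoter now matches through the scanner
  expect_true(all(iupac_match(again$sequence, "CWWWWWWWWG", "both")))
})
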