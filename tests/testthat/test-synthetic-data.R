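test_that("genome generation handles the minimal case and rejects infeasible packing", {
  cfg <- sim_config(n_genes = 1L, contig_length = 5000L, seed = 1)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$models), 1L)
  expect_equal(Biostrings::width(gen$genome)[[1]], 5000L)
  pr <- extract_promoters(gen$genome, gen$models)
  expect_equal(nrow(pr), 1L)
  expect_gte(pr$length, 1L)

  expect_error(
    generate_genome(sim_config(n_genes = 200L, contig_length = 4000L)),
    class = "viticre_sizing_error"
  )
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 40L, seed = 123)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$models, g2$models)
  c1 <- simulate_counts(cfg, g1$models)
  c2 <- simulate_counts(cfg, g2$models)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$de_table, c2$de_table)
})

test_that("every gene keeps a full-length promoter clear of its neighbours", {
  cfg <- sim_config(n_genes = 80L, seed = 6)
  gen <- generate_genome(cfg)
  m <- gen$models[order(gen$models$start), ]
  gaps <- m$start[-1] - m$end[-nrow(m)] - 1L
  expect_true(all(gaps >= cfg$promoter_length))
  expect_true(all(m$start[1] > cfg$promoter_length))
  pr <- extract_promoters(gen$genome, m)
  expect_true(all(pr$length == cfg$promoter_length))
  expect_true(all(!pr$clipped))
  expect_true(any(m$strand == "+") && any(m$strand == "-"))
})

test_that("NB counts degenerate to Poisson at zero dispersion", {
  cfg <- sim_config(n_genes = 10000L, contig_length = 3e7L,
                    nb_dispersion = 0, de_fraction = 0,
                    mean_expression_log_range = c(2, 2), seed = 9,
                    profile_noise_sd = 0)
  models <- data.frame(gene_id = sprintf("g%05d", 1:10000), contig = "c1",
                       start = 1L, end = 100L, strand = "+",
                       exonic_length = 100L)
  cts <- simulate_counts(cfg, models)
  draws <- cts$counts[, "small_47_1"]  # 10 000 draws at mean 100
  se <- sqrt(100 / 10000)
  expect_lt(abs(mean(draws) - 100), 3 * se)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.06)
})

test_that("NB sample variance tracks mean + dispersion * mean^2", {
  disp <- 0.1
  cfg <- sim_config(n_genes = 10000L, contig_length = 3e7L,
                    nb_dispersion = disp, de_fraction = 0,
                    mean_expression_log_range = c(2, 2),
                    profile_noise_sd = 0, seed = 14)
  models <- data.frame(gene_id = sprintf("g%05d", 1:10000), contig = "c1",
                       start = 1L, end = 100L, strand = "+",
                       exonic_length = 100L)
  cts <- simulate_counts(cfg, models)
  draws <- cts$counts[, "large_74_2"]
  expected_var <- 100 + disp * 100^2
  expect_lt(abs(var(draws) - expected_var) / expected_var, 0.1)
})

test_that("planted log2FC of 2 gives a pooled small/large ratio near 4", {
  arch <- matrix(2, 1, 4, dimnames = list(NULL, as.character(BERRY_STAGES)))
  cfg <- sim_config(n_genes = 2000L, contig_length = 6e6L, n_clusters = 1L,
                    profile_archetypes = arch, profile_noise_sd = 0,
                    de_fraction = 1, nb_dispersion = 0.05,
                    mean_expression_log_range = c(log10(500), log10(500)),
                    seed = 20)
  models <- data.frame(gene_id = sprintf("g%05d", 1:2000), contig = "c1",
                       start = 1L, end = 100L, strand = "+",
                       exonic_length = 100L)
  cts <- simulate_counts(cfg, models)
  info <- parse_sample_ids(colnames(cts$counts))
  small <- mean(cts$counts[, info$size == "small" & info$stage == 74])
  large <- mean(cts$counts[, info$size == "large" & info$stage == 74])
  expect_lt(abs(small / large - 4), 0.15)
})

test_that("truth tables cover exactly the simulated genes with consistent flags", {
  cfg <- sim_config(n_genes = 300L, seed = 77)
  gen <- generate_genome(cfg)
  cts <- simulate_counts(cfg, gen$models)
  expect_setequal(names(cts$truth$cluster_of_gene), gen$models$gene_id)
  de_genes <- names(cts$truth$cluster_of_gene)[!is.na(cts$truth$cluster_of_gene)]
  expect_equal(length(de_genes), round(cfg$de_fraction * 300))
  # per-stage truth sets match the fdr flags in the DE table
  sel <- select_de_genes(cts$de_table, alpha = 0.05)
  for (s in as.character(BERRY_STAGES)) {
    expect_setequal(sel$per_stage[[s]], cts$truth$de_genes_per_stage[[s]])
  }
  # every flagged gene is a planted DE gene
  expect_true(all(sel$union %in% de_genes))
})

test_that("BIN planting follows its enrichment factor and prefix closure", {
  genes <- sprintf("g%04d", 1:2000)
  clusters <- setNames(c(rep(1L, 100), rep(NA_integer_, 1900)), genes)
  rules <- data.frame(bin_code = "16.8", cluster = 1L, factor = 10)
  bins <- assign_bins(genes, catalog = c("16.8", "27.3"), rules = rules,
                      clusters = clusters, background_rate = 0.02, seed = 31)
  in_cluster <- bins$gene_id %in% genes[1:100] & bins$bin_code == "16.8"
  # factor 10, background 0.02, cluster of 100 -> expect about 20
  expect_lt(abs(sum(in_cluster) - 20), 3.3 * sqrt(100 * 0.2 * 0.8) + 1)
  # background rate for the unplanted BIN is ~2 %
  n_bg <- sum(bins$bin_code == "27.3")
  expect_lt(abs(n_bg - 40), 3.3 * sqrt(2000 * 0.02 * 0.98) + 1)
  # factor 1.0 null case: target and background rates statistically equal
  bins0 <- assign_bins(genes, catalog = "16.8",
                       rules = data.frame(bin_code = "16.8", cluster = 1L, factor = 1),
                       clusters = clusters, background_rate = 0.5, seed = 8)
  rate_t <- mean(genes[1:100] %in% bins0$gene_id)
  rate_b <- mean(genes[101:2000] %in% bins0$gene_id)
  expect_lt(abs(rate_t - rate_b), 0.17)  # > 3 s.e. of the difference
  # prefix closure through expansion
  expect_true("16" %in% expand_bin_prefixes("16.8"))
  expect_error(assign_bins(genes, catalog = "16.x"),
               class = "viticre_annotation_error")
})

test_that("motif planting respects probabilities, strand and recording", {
  n <- 60
  pr <- data.frame(gene_id = paste0("g", 1:n),
                   sequence = rand_test_seqs(n, 500, seed = 40),
                   length = 500L, clipped = FALSE)
  lib <- packaged_motif_library()
  clusters <- setNames(c(rep(1L, 10), rep(NA_integer_, n - 10)), pr$gene_id)
  # certainty planting in a 10-gene cluster
  rules <- data.frame(motif = "ABREATCONSENSUS", cluster = 1L,
                      p_target = 1, p_background = 0)
  planted <- plant_motifs(pr, lib, rules, clusters, seed = 4)
  target <- planted$promoters$gene_id %in% paste0("g", 1:10)
  expect_true(all(iupac_match(planted$promoters$sequence[target],
                              "YACGTGGC", "both")))
  expect_true(all(planted$sites$gene %in% paste0("g", 1:10)))
  # every recorded site lies inside its promoter and matches on re-scan
  w <- nchar("YACGTGGC")
  expect_true(all(planted$sites$offset >= 1 &
                  planted$sites$offset + w - 1 <= 500))
  for (i in seq_len(nrow(planted$sites))) {
    s <- planted$sites[i, ]
    window <- substr(planted$promoters$sequence[planted$promoters$gene_id == s$gene],
                     s$offset, s$offset + w - 1)
    onstrand <- if (s$strand == "+") window else oracle_revcomp(window)
    expect_identical(onstrand, s$instance)
  }
  # minus-strand-only planting is invisible to forward-only scanning
  rules2 <- data.frame(motif = "SORLIP5AT", cluster = 1L,
                       p_target = 1, p_background = 0)
  pr2 <- pr
  pr2$sequence <- gsub("GAGTGAG|CTCACTC", "AAAAAAA", pr2$sequence)
  planted2 <- plant_motifs(pr2, lib, rules2, clusters, seed = 6,
                           strand_mode = "minus")
  tseq <- planted2$promoters$sequence[target]
  expect_true(all(iupac_match(tseq, "GAGTGAG", "both")))
  expect_false(any(iupac_match(tseq, "GAGTGAG", "forward")))
  # a motif longer than the promoters is a rule error
  tiny <- data.frame(gene_id = "g1", sequence = "ACGT", length = 4L, clipped = FALSE)
  expect_error(
    plant_motifs(tiny, lib, rules, setNames(1L, "g1"), seed = 1),
    class = "viticre_rule_error"
  )
})
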