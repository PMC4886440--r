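#' Simulation configuration
#'
#' Bundles the geometry and signal parameters of the synthetic study:
#' `n_genes` genes on one contig, 1 kb promoters, two berry size classes
#' (small, large) sampled at four developmental stages (47, 74, 103,
#' 121 DAA) with three biological replicates, `n_clusters` planted log2
#' fold-change archetypes, negative-binomial counts, and motif/BIN
#' planting rules whose ground truth is recorded.
#'
#' @param n_genes number of genes to simulate.
#' @param contig_length contig length in bp (default 3000 bp per gene,
#'   leaving a full promoter plus flank in every gene's slot).
#' @param promoter_length promoter length in bp (default 1000).
#' @param n_clusters number of planted profile archetypes (default 8).
#' @param profile_archetypes matrix (`n_clusters` x 4) of log2FC values per
#'   stage; default [default_archetypes()].
#' @param profile_noise_sd per-stage Gaussian noise on planted log2FC
#'   (log2 units, default 0.3).
#' @param de_fraction fraction of genes that are differentially expressed
#'   (default 0.15, roughly the DE share of an expressed transcriptome).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mean + dispersion * mean^2); 0 degenerates to Poisson. Default 0.05.
#' @param mean_expression_log_range length-2 log10 range of baseline mean
#'   counts (default `c(-1, 3.5)`: from essentially undetected through
#'   highly expressed, so the expression filter has work to do).
#' @param motif_plant_rules data.frame with columns `motif`, `cluster`,
#'   `p_target`, `p_background` (see [plant_motifs()]); may be `NULL`.
#' @param bin_plant_rules data.frame with columns `bin_code`, `cluster`,
#'   `factor` (see [assign_bins()]); may be `NULL`.
#' @param de_min_l2fc |archetype log2FC| at which a planted-DE gene is
#'   flagged significant at a stage (default 1: with the default
#'   archetypes each DE gene is significant at two of the four stages,
#'   giving stage-specific DE sets and a structured Venn partition).
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       contig_length = 3000L * n_genes,
                       promoter_length = 1000L,
                       n_clusters = 8L,
                       profile_archetypes = default_archetypes(n_clusters),
                       profile_noise_sd = 0.3,
                       de_fraction = 0.15,
                       nb_dispersion = 0.05,
                       mean_expression_log_range = c(-1, 3.5),
                       motif_plant_rules = NULL,
                       bin_plant_rules = NULL,
                       de_min_l2fc = 1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), contig_length = as.integer(contig_length),
    promoter_length = as.integer(promoter_length),
    n_clusters = as.integer(n_clusters),
    profile_archetypes = profile_archetypes,
    profile_noise_sd = profile_noise_sd, de_fraction = de_fraction,
    nb_dispersion = nb_dispersion,
    mean_expression_log_range = mean_expression_log_range,
    motif_plant_rules = motif_plant_rules, bin_plant_rules = bin_plant_rules,
    de_min_l2fc = de_min_l2fc, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) vc_stop("viticre_parameter_error", "n_genes must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    vc_stop("viticre_parameter_error", "de_fraction must be in [0, 1]")
  if (cfg$nb_dispersion < 0)
    vc_stop("viticre_parameter_error", "nb_dispersion must be >= 0")
  if (!is.matrix(cfg$profile_archetypes) ||
      nrow(cfg$profile_archetypes) != cfg$n_clusters ||
      ncol(cfg$profile_archetypes) != length(BERRY_STAGES))
    vc_stop("viticre_parameter_error",
            "profile_archetypes must be an n_clusters x 4 matrix")
  if (!is.null(cfg$motif_plant_rules)) {
    pr <- cfg$motif_plant_rules
    if (any(pr$p_target < 0 | pr$p_target > 1 | pr$p_background < 0 | pr$p_background > 1))
      vc_stop("viticre_parameter_error", "plant probabilities must be in [0, 1]")
    if (any(pr$cluster < 1 | pr$cluster > cfg$n_clusters))
      vc_stop("viticre_parameter_error", "motif rule references unknown cluster")
  }
  if (!is.null(cfg$bin_plant_rules)) {
    validate_bin_codes(cfg$bin_plant_rules$bin_code)
    if (any(cfg$bin_plant_rules$factor < 0))
      vc_stop("viticre_parameter_error", "bin enrichment factor must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' Default log2 fold-change archetype profiles
#'
#' Eight 4-stage shapes (monotone up/down, early up/down with late
#' reversal, mid-development transients) chosen so that all eight have
#' distinct rank orderings across stages: Spearman similarity on
#' length-4 profiles only sees ranks, so rank-distinct archetypes are the
#' precondition for planted clusters to be recoverable at all.
#'
#' @param k number of archetypes (must be <= 8 for the defaults).
#' @return k x 4 numeric matrix, columns in stage order 47, 74, 103, 121.
#' @export
default_archetypes <- function(k = 8L) {
  shapes <- rbind(
    "monotone-down"  = c( 1.5,  0.5, -0.5, -1.5),
    "monotone-up"    = c(-1.5, -0.5,  0.5,  1.5),
    "late-peak-dip"  = c(-0.5,  1.5, -1.5,  0.5),
    "early-dip-peak" = c( 0.5, -1.5,  1.5, -0.5),
    "down-early"     = c( 1.5, -0.5, -1.5,  0.5),
    "up-mid"         = c(-1.5,  0.5,  1.5, -0.5),
    "transient-up"   = c(-0.5,  1.5,  0.5, -1.5),
    "transient-down" = c( 0.5, -1.5, -0.5,  1.5)
  )
  if (k > nrow(shapes))
    vc_stop("viticre_parameter_error", "only ", nrow(shapes), " default archetypes available")
  m <- shapes[seq_len(k), , drop = FALSE]
  colnames(m) <- as.character(BERRY_STAGES)
  m
}

#' Generate a synthetic genome and gene annotation
#'
#' Places `n_genes` genes on a single contig of i.i.d. uniform A/C/G/T
#' sequence using fixed-pitch slots with jitter: every gene keeps at least
#' `promoter_length` bp clear of its neighbours on both sides, so a
#' full-length promoter is always extractable. Genes fall on both strands.
#' Deterministic for a fixed config (seeded from `config$seed`).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a one-contig [Biostrings::DNAStringSet])
#'   and `models` (gene-model data.frame as from [read_gene_models()]).
#' @export
generate_genome <- function(config) {
  n <- config$n_genes
  pitch <- config$contig_length %/% n
  min_len <- 300L
  if (pitch < 2L * config$promoter_length + min_len)
    vc_stop("viticre_sizing_error",
            "contig_length too small: pitch ", pitch, " bp per gene cannot hold ",
            "a gene plus ", config$promoter_length, " bp promoter flanks")
  max_len <- min(900L, pitch - 2L * config$promoter_length)
  withr::with_seed(config$seed, {
    contig <- rand_dna(config$contig_length)
    len <- sample(min_len:max_len, n, replace = TRUE)
    slack <- pitch - 2L * config$promoter_length - len
    jitter <- vapply(slack, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
    start <- (seq_len(n) - 1L) * pitch + config$promoter_length + 1L + jitter
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  models <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    contig = "chr1",
    start = start,
    end = start + len - 1L,
    strand = strand,
    exonic_length = len,
    stringsAsFactors = FALSE
  )
  list(genome = Biostrings::DNAStringSet(c(chr1 = contig)), models = models)
}

# i.i.d. random DNA string(s); gc = P(G or C)
rand_dna <- function(len, n = 1L, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  if (n == 1L) out[[1L]] else out
}

# random concrete instance of an IUPAC pattern (N expands over A/C/G/T)
random_iupac_instance <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1L]]]
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

#' Plant motif instances into promoter sequences
#'
#' For each rule, promoters of genes in the rule's target cluster receive
#' at least one implanted exact instance of the motif (a random concrete
#' expansion of the IUPAC pattern, random strand, random offset) with
#' probability `p_target`; all other promoters receive one with
#' probability `p_background`. Implants never overwrite one another; every
#' implant is recorded with its gene, offset (1-based, promoter
#' coordinates), strand relative to the promoter, and concrete instance.
#'
#' @param promoters promoter data.frame as from [extract_promoters()].
#' @param library motif library data.frame ([read_motif_library()]).
#' @param rules data.frame with columns `motif` (name in `library`),
#'   `cluster`, `p_target`, `p_background`.
#' @param clusters named vector mapping gene_id to cluster id (NA for
#'   genes in no cluster).
#' @param seed integer seed.
#' @param strand_mode `"random"` (default) picks each implant's strand at
#'   random; `"plus"` or `"minus"` force one strand (useful for strand-
#'   handling tests).
#' @return list with `promoters` (modified copy) and `sites` (data.frame
#'   gene, motif, offset, strand, instance).
#' @export
plant_motifs <- function(promoters, library, rules, clusters, seed = 1L,
                         strand_mode = c("random", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(all(c("motif", "cluster", "p_target", "p_background") %in% names(rules)))
  unknown <- setdiff(rules$motif, library$name)
  if (length(unknown))
    vc_stop("viticre_rule_error", "rule motif(s) not in library: ",
            paste(unknown, collapse = ", "))
  seqs <- promoters$sequence
  occupied <- vector("list", nrow(promoters))
  sites <- list()
  withr::with_seed(seed, {
    for (r in seq_len(nrow(rules))) {
      pattern <- library$pattern[match(rules$motif[r], library$name)]
      w <- nchar(pattern)
      if (any(w > promoters$length))
        vc_stop("viticre_rule_error", "motif ", rules$motif[r],
                " longer than shortest promoter")
      in_target <- !is.na(clusters[promoters$gene_id]) &
        clusters[promoters$gene_id] == rules$cluster[r]
      p <- ifelse(in_target, rules$p_target[r], rules$p_background[r])
      plant <- stats::runif(nrow(promoters)) < p
      for (i in which(plant)) {
        free <- setdiff(seq_len(promoters$length[i] - w + 1L),
                        unlist(lapply(occupied[[i]], function(iv) {
                          (iv[1] - w + 1L):iv[2]
                        })))
        free <- free[free >= 1L]
        if (!length(free)) next  # promoter saturated; skip, do not record
        offset <- free[sample.int(length(free), 1L)]
        strand <- switch(strand_mode,
                         random = sample(c("+", "-"), 1L),
                         plus = "+", minus = "-")
        inst <- random_iupac_instance(pattern)
        put <- if (strand == "+") inst else reverse_complement(inst)
        substr(seqs[i], offset, offset + w - 1L) <- put
        occupied[[i]] <- c(occupied[[i]], list(c(offset, offset + w - 1L)))
        sites[[length(sites) + 1L]] <- data.frame(
          gene = promoters$gene_id[i], motif = rules$motif[r],
          offset = offset, strand = strand, instance = inst,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  promoters$sequence <- seqs
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(gene = character(), motif = character(), offset = integer(),
               strand = character(), instance = character(), stringsAsFactors = FALSE)
  list(promoters = promoters, sites = sites)
}

#' Simulate a negative-binomial count matrix with planted DE structure
#'
#' Draws counts for 24 samples (2 size classes x 4 stages x 3 replicates)
#' from NB(mean, dispersion) with variance mean + dispersion * mean^2;
#' dispersion 0 degenerates to Poisson. A `de_fraction` subset of genes is
#' assigned a planted archetype cluster; at each stage the small/large
#' class-mean ratio of such a gene equals `2^(archetype log2FC + noise)`,
#' split symmetrically around its baseline mean. The returned truth
#' DETable carries the realised log2FC and a deterministic significance
#' flag (fdr 1e-4 where |archetype| >= `de_min_l2fc`, else 0.5), standing
#' in for an external differential-expression test.
#'
#' @param config a [sim_config()].
#' @param models gene-model data.frame; genes simulated in its row order.
#' @return list with `counts` (integer matrix), `samples` (metadata
#'   data.frame), `de_table` (gene, stage, log2fc, fdr), and `truth`
#'   (list: `cluster_of_gene` named vector with NA for non-DE genes,
#'   `de_genes_per_stage` named list of gene sets).
#' @export
simulate_counts <- function(config, models) {
  n <- nrow(models)
  genes <- models$gene_id
  stages <- BERRY_STAGES
  samples <- expand.grid(rep = 1:3, stage = stages, size = BERRY_SIZES,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("size", "stage", "rep")]
  samples$sample <- sprintf("%s_%d_%d", samples$size, samples$stage, samples$rep)
  withr::with_seed(config$seed + 1L, {
    n_de <- round(config$de_fraction * n)
    de_genes <- sort(sample.int(n, n_de))
    cluster_of_gene <- setNames(rep(NA_integer_, n), genes)
    cluster_of_gene[de_genes] <-
      sample(rep_len(seq_len(config$n_clusters), max(n_de, 1L))[seq_len(n_de)])
    lr <- config$mean_expression_log_range
    base_mean <- 10^stats::runif(n, lr[1], lr[2])
    # realised log2FC per gene x stage: archetype + noise for DE genes,
    # pure noise around zero otherwise
    l2fc <- matrix(stats::rnorm(n * length(stages), 0, config$profile_noise_sd),
                   n, length(stages), dimnames = list(genes, as.character(stages)))
    arch <- matrix(0, n, length(stages))
    arch[de_genes, ] <- config$profile_archetypes[cluster_of_gene[de_genes], , drop = FALSE]
    l2fc <- l2fc + arch
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      s <- match(as.character(samples$stage[j]), colnames(l2fc))
      shift <- if (samples$size[j] == "small") l2fc[, s] / 2 else -l2fc[, s] / 2
      mu <- base_mean * 2^shift
      if (any(mu < 0)) vc_stop("viticre_parameter_error", "negative NB mean")
      counts[, j] <- if (config$nb_dispersion == 0) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      }
    }
  })
  sig <- matrix(FALSE, n, length(stages))
  sig[de_genes, ] <- abs(arch[de_genes, , drop = FALSE]) >= config$de_min_l2fc
  de_table <- data.frame(
    gene = rep(genes, times = length(stages)),
    stage = rep(stages, each = n),
    log2fc = as.vector(l2fc),
    fdr = ifelse(as.vector(sig), 1e-4, 0.5),
    stringsAsFactors = FALSE
  )
  de_sets <- lapply(seq_along(stages), function(s) genes[sig[, s]])
  names(de_sets) <- as.character(stages)
  list(counts = counts, samples = samples, de_table = de_table,
       truth = list(cluster_of_gene = cluster_of_gene,
                    de_genes_per_stage = de_sets))
}

#' Default MapMan-style BIN catalog
#'
#' A small hierarchical catalog of plant functional categories in the
#' MapMan numbering convention (cell wall, hormone metabolism, secondary
#' metabolism and its flavonoid branch, RNA regulation, signalling,
#' transport, stress, development, fermentation, misc, metal handling).
#' Leaf codes imply their prefixes (a gene in 16.8 also counts for 16).
#'
#' @return character vector of leaf BIN codes.
#' @export
default_bin_catalog <- function() {
  c("5.3", "10.2", "10.6", "10.7", "10.8", "15.1", "16.1", "16.8",
    "17.1", "17.2", "17.5", "18.2", "20.2", "25.3", "26.28", "27.3",
    "29.5", "30.2", "30.3", "33.1", "33.99", "34.4", "34.12", "35.1")
}

#' Assign BIN annotations with planted per-cluster enrichment
#'
#' Every gene receives each catalog BIN independently at `background_rate`;
#' genes in a rule's target cluster receive the rule's BIN at
#' `factor * background_rate` instead (capped at 1). Annotation is by leaf
#' code; membership is prefix-closed downstream (a gene annotated 16.8
#' also tests positive for 16).
#'
#' @param genes character vector of gene ids.
#' @param catalog character vector of leaf BIN codes.
#' @param rules data.frame with columns `bin_code`, `cluster`, `factor`,
#'   or NULL for no planted enrichment.
#' @param clusters named gene-to-cluster vector (NA allowed).
#' @param background_rate baseline annotation probability per (gene, BIN)
#'   (default 0.02).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `bin_code`.
#' @export
assign_bins <- function(genes, catalog = default_bin_catalog(), rules = NULL,
                        clusters = NULL, background_rate = 0.02, seed = 1L) {
  validate_bin_codes(catalog)
  if (!is.null(rules)) validate_bin_codes(rules$bin_code)
  out <- withr::with_seed(seed, {
    res <- lapply(catalog, function(code) {
      p <- rep(background_rate, length(genes))
      if (!is.null(rules)) {
        for (r in which(rules$bin_code == code)) {
          hit <- !is.na(clusters[genes]) & clusters[genes] == rules$cluster[r]
          p[hit] <- min(1, background_rate * rules$factor[r])
        }
      }
      got <- stats::runif(length(genes)) < p
      data.frame(gene_id = genes[got], bin_code = rep(code, sum(got)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out[order(out$gene_id, out$bin_code), , drop = FALSE]
}
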