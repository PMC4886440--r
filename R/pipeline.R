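#' Default run configuration
#'
#' Flat key-value configuration of a full pipeline run over synthetic
#' data. Thresholds carry the study defaults: DE at FDR < 0.05, BIN
#' enrichment at Bonferroni-adjusted p < 0.05, motif enrichment at
#' FDR < 0.01, expression filter at FPKM < 0.5 and counts < 5, k = 8
#' clusters with a 1000-iteration cap, 1 kb promoters scanned on both
#' strands.
#'
#' @param seed master seed for the run.
#' @return named list of configuration values.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    # simulation geometry
    n_genes = 2000L, promoter_length = 1000L, n_clusters = 8L,
    de_fraction = 0.15, profile_noise_sd = 0.3, nb_dispersion = 0.05,
    bin_background_rate = 0.02,
    # thresholds
    de_alpha = 0.05, bin_alpha = 0.05, motif_fdr = 0.01,
    fpkm_min = 0.5, count_min = 5,
    # clustering
    k = 8L, max_iterations = 1000L, restarts = 10L,
    # promoter scanning
    strands = "both",
    # planted signal (motif name -> cluster; BIN code -> cluster)
    # planted motifs chosen with unsaturated background presence in
    # uniform 1 kb promoters, so presence/absence enrichment has power
    motif_rules = data.frame(
      motif = c("CACGTGMOTIF", "ABREATCONSENSUS", "TCP15", "ETT-1"),
      cluster = c(1L, 2L, 5L, 6L),
      p_target = 0.6, p_background = 0.08, stringsAsFactors = FALSE
    ),
    bin_rules = data.frame(
      bin_code = c("16.8", "10.6", "17.1"),
      cluster = c(1L, 4L, 6L), factor = 10, stringsAsFactors = FALSE
    ),
    seed = as.integer(seed)
  )
}

#' Load a run configuration from a YAML file
#'
#' Flat keys as in [default_run_config()]; unspecified keys take their
#' defaults. The planted-signal tables may be given as lists of records.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) vc_stop("viticre_config_error", "no such config file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    val <- user[[nm]]
    if (nm %in% c("motif_rules", "bin_rules") && is.list(val) && !is.data.frame(val))
      val <- do.call(rbind, lapply(val, as.data.frame, stringsAsFactors = FALSE))
    cfg[[nm]] <- val
  }
  cfg
}

#' Validate a run configuration
#'
#' Range-checks every threshold, fills defaults, and (when input paths
#' are present) checks that they exist. All violations are reported
#' together, each naming the offending field.
#'
#' @param config configuration list (possibly partial).
#' @return the validated, completed configuration.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  for (f in c("de_alpha", "bin_alpha", "motif_fdr")) {
    v <- cfg[[f]]
    chk(is.numeric(v) && length(v) == 1 && v > 0 && v <= 1,
        paste0(f, ": must be in (0, 1]"))
  }
  chk(cfg$fpkm_min >= 0, "fpkm_min: must be >= 0")
  chk(cfg$count_min >= 0, "count_min: must be >= 0")
  chk(is.numeric(cfg$k) && cfg$k >= 1, "k: must be >= 1")
  chk(cfg$max_iterations >= 1, "max_iterations: must be >= 1")
  chk(cfg$restarts >= 1, "restarts: must be >= 1")
  chk(cfg$promoter_length >= 1, "promoter_length: must be >= 1")
  chk(cfg$strands %in% c("both", "forward"), "strands: must be 'both' or 'forward'")
  chk(cfg$n_genes >= 1, "n_genes: must be >= 1")
  for (f in c("genome", "gff", "counts", "de_table", "bins", "motifs")) {
    p <- cfg[[paste0("path_", f)]]
    if (!is.null(p)) chk(file.exists(p), paste0("paths.", f, ": file not found: ", p))
  }
  if (length(errs))
    vc_stop("viticre_config_error", "invalid configuration:\n  ",
            paste(errs, collapse = "\n  "))
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> express -> cluster -> enrich as one reproducible
#' run: generates a genome, annotation, promoters with planted motifs,
#' NB counts with planted DE/cluster structure and BIN annotations with
#' planted enrichment; computes FPKM and applies the expression filter;
#' selects per-stage DE genes and the Venn partition; builds the log2FC
#' matrix and clusters it (k-means, Spearman similarity); and computes
#' BIN and promoter-CRE enrichment. All artifacts (and the ground truth)
#' are written to `outdir` as TSV/FASTA/GFF3, plus a machine-readable
#' manifest (`manifest.json`) with the effective config, seed, package
#' version, and per-file md5 checksums. Re-running with the same config
#' and seed reproduces every file byte-identically.
#'
#' @param config configuration list (see [default_run_config()]); it is
#'   validated first.
#' @param outdir output directory (created if needed).
#' @param motif_library motif library data.frame; default the packaged
#'   PLACE/PBM set.
#' @return (invisibly) a list with the main in-memory results and the
#'   path of the run directory.
#' @export
run_pipeline <- function(config = default_run_config(), outdir,
                         motif_library = packaged_motif_library()) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      vc_stop("viticre_stage_failure", "stage '", name, "' failed: ",
              conditionMessage(e))
    })
  }

  sim_cfg <- sim_config(
    n_genes = cfg$n_genes, promoter_length = cfg$promoter_length,
    n_clusters = cfg$n_clusters, de_fraction = cfg$de_fraction,
    profile_noise_sd = cfg$profile_noise_sd, nb_dispersion = cfg$nb_dispersion,
    motif_plant_rules = cfg$motif_rules, bin_plant_rules = cfg$bin_rules,
    seed = cfg$seed
  )

  sim <- stage("simulate", {
    gen <- generate_genome(sim_cfg)
    cts <- simulate_counts(sim_cfg, gen$models)
    promoters <- extract_promoters(gen$genome, gen$models, cfg$promoter_length)
    planted <- plant_motifs(promoters, motif_library, cfg$motif_rules,
                            cts$truth$cluster_of_gene, seed = cfg$seed + 2L)
    genome <- patch_genome_with_promoters(gen$genome, gen$models,
                                          planted$promoters, cfg$promoter_length)
    bins <- assign_bins(gen$models$gene_id, default_bin_catalog(),
                        cfg$bin_rules, cts$truth$cluster_of_gene,
                        background_rate = cfg$bin_background_rate,
                        seed = cfg$seed + 3L)
    write_genome_fasta(genome, pth("genome.fasta"))
    write_gene_models(gen$models, pth("genes.gff3"))
    write_count_matrix(cts$counts, pth("counts.tsv"))
    write_de_table(cts$de_table, pth("de_truth.tsv"))
    write_bin_annotation(bins, pth("bins.tsv"))
    write_tsv(planted$sites, pth("planted_sites.tsv"))
    truth_clusters <- data.frame(
      gene = names(cts$truth$cluster_of_gene),
      cluster = unname(cts$truth$cluster_of_gene), stringsAsFactors = FALSE
    )
    write_tsv(truth_clusters, pth("truth_clusters.tsv"))
    list(genome = genome, models = gen$models, counts = cts$counts,
         de_table = cts$de_table, truth = cts$truth, bins = bins,
         promoters = planted$promoters, sites = planted$sites)
  })

  expr <- stage("express", {
    fpkm <- compute_fpkm(sim$counts, sim$models)
    filt <- filter_expressed(fpkm, sim$counts, cfg$fpkm_min, cfg$count_min)
    write_tsv(filt$report, pth("filter_report.tsv"))
    de_tab <- sim$de_table[sim$de_table$gene %in% filt$retained, , drop = FALSE]
    de <- select_de_genes(de_tab, cfg$de_alpha)
    if (length(de$union) == 0L)
      warning("no significant DE genes; downstream tables will be empty")
    venn <- venn_partition(de$per_stage)
    write_tsv(venn, pth("venn_counts.tsv"))
    de_sets <- do.call(rbind, lapply(names(de$per_stage), function(s) {
      if (!length(de$per_stage[[s]])) return(NULL)
      data.frame(stage = s, gene = de$per_stage[[s]], stringsAsFactors = FALSE)
    }))
    write_tsv(de_sets %||% data.frame(stage = character(), gene = character()),
              pth("de_sets.tsv"))
    fc <- if (length(de$union)) build_foldchange_matrix(de_tab, de$union) else
      matrix(numeric(), 0, 4, dimnames = list(NULL, as.character(BERRY_STAGES)))
    write_tsv(data.frame(gene = rownames(fc), fc, check.names = FALSE),
              pth("foldchange_matrix.tsv"))
    list(fpkm = fpkm, retained = filt$retained, de = de, fc = fc)
  })

  clus <- stage("cluster", {
    if (nrow(expr$fc) >= cfg$k) {
      fit <- kmeans_correlation(expr$fc, k = cfg$k,
                                max_iterations = cfg$max_iterations,
                                restarts = cfg$restarts, seed = cfg$seed + 4L)
      write_tsv(data.frame(gene = names(fit$labels),
                           cluster = unname(fit$labels)), pth("clusters.tsv"))
      write_tsv(data.frame(cluster = seq_len(cfg$k), fit$centroids,
                           check.names = FALSE), pth("centroids.tsv"))
      fit
    } else {
      warning("fewer DE genes than k; skipping clustering")
      write_tsv(data.frame(gene = character(), cluster = integer()),
                pth("clusters.tsv"))
      NULL
    }
  })

  bin_enr <- stage("enrich-bins", {
    res <- if (!is.null(clus)) {
      enrich_bins(clus$labels, sim$bins, background = expr$retained,
                  alpha = cfg$bin_alpha)
    } else empty_enrichment()
    write_enrichment_table(res, pth("bin_enrichment.tsv"))
    res
  })

  motif_enr <- stage("enrich-motifs", {
    res <- if (!is.null(clus)) {
      enrich_motifs(clus$labels, sim$promoters, motif_library,
                    strands = cfg$strands, fdr_threshold = cfg$motif_fdr)
    } else empty_enrichment()
    write_enrichment_table(res, pth("motif_enrichment.tsv"))
    pres <- motif_presence_matrix(sim$promoters, motif_library, cfg$strands)
    write_tsv(data.frame(gene = rownames(pres), pres, check.names = FALSE),
              pth("motif_presence.tsv"))
    res
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(outdir), "manifest.json"))
    md5 <- tools::md5sum(file.path(outdir, files))
    man <- list(
      package = "viticre",
      version = as.character(utils::packageVersion("viticre")),
      seed = cfg$seed,
      config = cfg[order(names(cfg))],
      files = setNames(as.list(unname(md5)), files)
    )
    jsonlite::write_json(man, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, dataframe = "rows")
    man
  })

  invisible(list(outdir = outdir, config = cfg, sim = sim, expression = expr,
                 clustering = clus, bin_enrichment = bin_enr,
                 motif_enrichment = motif_enr, manifest = manifest))
}

empty_enrichment <- function() {
  data.frame(set_id = character(), term = character(), k = integer(),
             n = integer(), K = integer(), N = integer(), p_raw = numeric(),
             p_adjusted = numeric(), enriched = logical(),
             stringsAsFactors = FALSE)
}
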