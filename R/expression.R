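#' Compute FPKM from a count matrix
#'
#' FPKM = count / (exonic_length / 1000) / (library_size / 1e6), i.e.
#' fragments per kilobase of exon per million assigned fragments. Library
#' sizes default to per-sample assigned-fragment totals (column sums).
#'
#' @param counts integer matrix, genes x samples.
#' @param models gene-model data.frame supplying `exonic_length` per gene.
#' @param library_sizes per-sample fragment totals (default `colSums(counts)`).
#' @return numeric matrix of FPKM values with the same axes.
#' @export
compute_fpkm <- function(counts, models, library_sizes = colSums(counts)) {
  missing <- setdiff(rownames(counts), models$gene_id)
  if (length(missing))
    vc_stop("viticre_keyed_error", "gene(s) missing from annotation: ",
            paste(utils::head(missing, 10L), collapse = ", "))
  len <- models$exonic_length[match(rownames(counts), models$gene_id)]
  if (any(len < 1L)) vc_stop("viticre_parameter_error", "exonic_length must be >= 1")
  if (any(library_sizes <= 0)) vc_stop("viticre_parameter_error", "library sizes must be > 0")
  sweep(counts / (len / 1000), 2, library_sizes / 1e6, "/")
}

#' Filter lowly expressed genes
#'
#' Mirrors the discard rule "FPKM < 0.5 and assigned counts < 5": a gene
#' is discarded iff its aggregated FPKM is below `fpkm_min` AND its
#' aggregated count is below `count_min` (both conditions, the
#' conservative reading). Aggregation across samples is the per-gene
#' maximum by default; both the AND/OR combination and the aggregation
#' are switchable.
#'
#' @param fpkm FPKM matrix.
#' @param counts count matrix on the same axes.
#' @param fpkm_min FPKM threshold (default 0.5, strict <).
#' @param count_min count threshold (default 5, strict <).
#' @param combine `"and"` (default) or `"or"`: how the two below-threshold
#'   conditions combine into a discard.
#' @param aggregate `"max"` (default) or `"mean"` across samples.
#' @return list with `retained` (gene ids) and `report` (per-gene
#'   data.frame: gene, agg_fpkm, agg_count, retained, reason).
#' @export
filter_expressed <- function(fpkm, counts, fpkm_min = 0.5, count_min = 5,
                             combine = c("and", "or"),
                             aggregate = c("max", "mean")) {
  combine <- match.arg(combine)
  aggregate <- match.arg(aggregate)
  if (!identical(dim(fpkm), dim(counts)) ||
      !identical(rownames(fpkm), rownames(counts)))
    vc_stop("viticre_shape_error", "fpkm and counts matrices must share axes")
  agg <- if (aggregate == "max") function(m) apply(m, 1, max) else rowMeans
  af <- agg(fpkm)
  ac <- agg(counts)
  low_f <- af < fpkm_min
  low_c <- ac < count_min
  discard <- if (combine == "and") low_f & low_c else low_f | low_c
  report <- data.frame(
    gene = rownames(fpkm), agg_fpkm = af, agg_count = ac,
    retained = !discard,
    reason = ifelse(discard,
                    paste0(ifelse(low_f, "low_fpkm", ""),
                           ifelse(low_f & low_c, "+", ""),
                           ifelse(low_c, "low_count", "")),
                    "."),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(retained = rownames(fpkm)[!discard], report = report)
}

#' Select differentially expressed genes per stage
#'
#' A gene is DE at a stage iff its FDR there is strictly below `alpha`
#' (boundary values excluded). Also splits each stage's set by the sign
#' of log2FC (positive = up in small berries) and returns the union
#' across stages.
#'
#' @param de DE table data.frame (`gene`, `stage`, `log2fc`, `fdr`).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `per_stage` (named list of gene-id vectors, one per
#'   stage present in `de`), `up`, `down` (same structure), and `union`.
#' @export
select_de_genes <- function(de, alpha = 0.05) {
  stages <- sort(unique(de$stage))
  sel <- function(cond) {
    out <- lapply(stages, function(s) unique(de$gene[de$stage == s & cond]))
    names(out) <- as.character(stages)
    out
  }
  sig <- de$fdr < alpha
  per_stage <- sel(sig)
  list(
    per_stage = per_stage,
    up = sel(sig & de$log2fc > 0),
    down = sel(sig & de$log2fc < 0),
    union = unique(unlist(per_stage, use.names = FALSE))
  )
}

#' Venn partition of up to four gene sets
#'
#' Assigns each member of the union to exactly one of the 2^m - 1
#' membership regions and counts region sizes; counts sum to the union
#' size.
#'
#' @param sets named list of at most 4 character vectors.
#' @return data.frame with columns `region` (set names joined by `&`) and
#'   `count`, one row per non-empty membership pattern (all patterns
#'   listed, including zero counts).
#' @export
venn_partition <- function(sets) {
  if (length(sets) > 4L) vc_stop("viticre_parameter_error", "at most 4 sets")
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)),
                          KEEP.OUT.ATTRS = FALSE)[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  key <- if (length(universe)) apply(memb, 1, paste, collapse = "") else character()
  pkey <- apply(patterns, 1, paste, collapse = "")
  counts <- as.integer(table(factor(key, levels = pkey)))
  region <- vapply(seq_len(nrow(patterns)), function(i) {
    paste(names(sets)[unlist(patterns[i, ])], collapse = "&")
  }, character(1))
  data.frame(region = region, count = counts, stringsAsFactors = FALSE)
}

#' Build the DE-gene log2 fold-change matrix
#'
#' Rows are the given genes, columns the four developmental stages in
#' order 47, 74, 103, 121 DAA; values are log2FC (small/large) taken from
#' the DE table. Every gene must have a value at every stage.
#'
#' @param de DE table data.frame.
#' @param genes character vector of gene ids (typically the DE union).
#' @return numeric matrix genes x 4.
#' @export
build_foldchange_matrix <- function(de, genes) {
  stages <- BERRY_STAGES
  m <- matrix(NA_real_, length(genes), length(stages),
              dimnames = list(genes, as.character(stages)))
  sub <- de[de$gene %in% genes, , drop = FALSE]
  idx <- cbind(match(sub$gene, genes), match(sub$stage, stages))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- sub$log2fc[keep]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    vc_stop("viticre_completeness_error",
            "missing log2FC for ", nrow(miss), " (gene, stage) pair(s), e.g. ",
            genes[miss[1, 1]], " at ", stages[miss[1, 2]], " DAA")
  }
  m
}

#' Per-stage mean log2(FPKM + 1) expression
#'
#' The mean over all samples of a stage (both size classes, all
#' replicates) of log2(FPKM + 1): the developmental expression trajectory
#' used alongside fold-change profiles.
#'
#' @param fpkm FPKM matrix with `size_stage_rep` column names.
#' @return numeric matrix genes x stages.
#' @export
stage_mean_log_expression <- function(fpkm) {
  info <- parse_sample_ids(colnames(fpkm))
  stages <- sort(unique(info$stage))
  out <- vapply(stages, function(s) {
    rowMeans(log2(fpkm[, info$stage == s, drop = FALSE] + 1))
  }, numeric(nrow(fpkm)))
  out <- matrix(out, nrow = nrow(fpkm),
                dimnames = list(rownames(fpkm), as.character(stages)))
  out
}
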