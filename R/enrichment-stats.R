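# validate hypergeometric contingency counts:
# k hits in a sample of n, K hits in a background of N
check_contingency <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0 | N < 1 |
    k < pmax(0, n + K - N)
  if (any(bad))
    vc_stop("viticre_parameter_error",
            "invalid contingency counts (need max(0, n+K-N) <= k <= min(n, K), n <= N, K <= N)")
  invisible(TRUE)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with `K` marked items among `N`, drawing
#' `n`. Computed in log space (via the stable tail routine underlying
#' [stats::phyper]); identical to the one-sided (greater) Fisher exact
#' p-value of the corresponding 2x2 table. Vectorized over `k`, `n`, `K`.
#'
#' @param k hits in the sample.
#' @param n sample size.
#' @param K hits in the background.
#' @param N background size.
#' @return numeric vector of upper-tail probabilities.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' One-sided (enrichment) Fisher exact test
#'
#' The greater-tail Fisher exact p-value of the 2x2 table implied by the
#' counts; equal to [hypergeom_tail()] for the enrichment direction.
#'
#' @inheritParams hypergeom_tail
#' @return numeric vector of p-values.
#' @export
fisher_one_sided <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  mapply(function(k, n, K, N) {
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, k, n, K, N)
}

#' Bonferroni family-wise correction
#'
#' `min(1, m * p)` per element, where `m` is the number of tests in the
#' family (default: the length of `p`).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m family size.
#' @return adjusted p-values, same order as input.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    vc_stop("viticre_parameter_error", "p-values must be in [0, 1]")
  pmin(1, m * p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard BH with monotonicity enforcement; input order preserved.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (q-values), same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    vc_stop("viticre_parameter_error", "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Expand a BIN code into itself plus all its prefixes
#'
#' `"10.6.2"` expands to `c("10", "10.6", "10.6.2")`: the hierarchical
#' closure underlying MapMan membership (a gene annotated to a child BIN
#' belongs to every ancestor BIN).
#'
#' @param codes character vector of dot-separated numeric BIN codes.
#' @return character vector of unique expanded codes.
#' @export
expand_bin_prefixes <- function(codes) {
  validate_bin_codes(codes)
  out <- unlist(lapply(strsplit(codes, ".", fixed = TRUE), function(parts) {
    vapply(seq_along(parts), function(d) paste(parts[1:d], collapse = "."),
           character(1))
  }))
  unique(out)
}

bin_depth <- function(codes) lengths(strsplit(codes, ".", fixed = TRUE))

# sortable key: numeric components zero-padded
bin_sort_key <- function(codes) {
  vapply(strsplit(codes, ".", fixed = TRUE), function(p) {
    paste(sprintf("%06d", as.integer(p)), collapse = ".")
  }, character(1))
}

#' MapMan-BIN overrepresentation per gene cluster
#'
#' For every cluster and every prefix-expanded BIN term (depth <=
#' `max_depth`) with at least one hit in the cluster, tests enrichment of
#' the cluster against the background gene universe with the one-sided
#' Fisher exact test (hypergeometric tail) and applies Bonferroni
#' correction within the cluster, counting only the tested terms. A term
#' is called enriched when its adjusted p-value is below `alpha`
#' (default 0.05). Output is sorted by cluster, then BIN code.
#'
#' @param clusters named list of gene-id vectors, or a named
#'   gene-to-cluster label vector (NA labels ignored).
#' @param bins BIN annotation data.frame (`gene_id`, `bin_code`).
#' @param background character vector: the background gene universe
#'   (e.g. all expressed, annotated genes). Cluster genes must be a
#'   subset of it.
#' @param alpha enrichment threshold on the adjusted p-value.
#' @param max_depth maximum BIN depth tested (default Inf = all levels).
#' @return data.frame with columns `set_id`, `term`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_adjusted` (Bonferroni), `enriched`.
#' @export
enrich_bins <- function(clusters, bins, background, alpha = 0.05,
                        max_depth = Inf) {
  if (!is.list(clusters)) {
    labs <- clusters[!is.na(clusters)]
    clusters <- split(names(labs), labs)
  }
  stray <- setdiff(unlist(clusters), background)
  if (length(stray))
    vc_stop("viticre_consistency_error",
            "cluster gene(s) missing from background: ",
            paste(utils::head(stray, 5L), collapse = ", "))
  ann <- bins[bins$gene_id %in% background, , drop = FALSE]
  # prefix-closed membership: gene -> all expanded codes
  expanded <- lapply(strsplit(ann$bin_code, ".", fixed = TRUE), function(p) {
    vapply(seq_along(p), function(d) paste(p[1:d], collapse = "."), character(1))
  })
  memb <- unique(data.frame(
    gene_id = rep(ann$gene_id, lengths(expanded)),
    term = unlist(expanded), stringsAsFactors = FALSE
  ))
  memb <- memb[bin_depth(memb$term) <= max_depth, , drop = FALSE]
  genes_of_term <- split(memb$gene_id, memb$term)
  N <- length(background)
  K_all <- vapply(genes_of_term, length, integer(1))
  out <- list()
  for (cl in names(clusters)) {
    cg <- clusters[[cl]]
    n <- length(cg)
    k <- vapply(genes_of_term, function(g) length(intersect(g, cg)), integer(1))
    tested <- which(k >= 1L)
    if (!length(tested)) next
    p <- hypergeom_tail(k[tested], n = n, K = K_all[tested], N = N)
    padj <- bonferroni(p, m = length(tested))
    out[[cl]] <- data.frame(
      set_id = cl, term = names(genes_of_term)[tested],
      k = as.integer(k[tested]), n = n, K = as.integer(K_all[tested]), N = N,
      p_raw = p, p_adjusted = padj, enriched = padj < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (!length(out))
    return(data.frame(set_id = character(), term = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$set_id, bin_sort_key(res$term)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
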