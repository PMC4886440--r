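#' Spearman rank-correlation similarity of two profiles
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' If either profile is constant the rank correlation is undefined; by
#' convention the similarity is 0 and a warning is emitted.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return similarity in \[-1, 1\].
#' @export
spearman_similarity <- function(x, y) {
  if (length(x) != length(y))
    vc_stop("viticre_shape_error", "profiles must have equal length")
  if (length(x) < 2L)
    vc_stop("viticre_shape_error", "profiles must have length >= 2")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant profile: Spearman similarity undefined, returning 0")
    return(0)
  }
  stats::cor(rx, ry)
}

# rank each row (average ranks for ties)
rank_rows <- function(m) t(apply(m, 1, rank))

# standardize rows to zero mean / unit sd (sd with n-1); constant rows -> 0
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  z <- ctr / ifelse(s == 0, Inf, s)
  z
}

# n x k similarity matrix between profile rows and centroid rows
similarity_matrix <- function(profiles, centroids, metric) {
  if (metric == "spearman") {
    profiles <- rank_rows(profiles)
    centroids <- rank_rows(centroids)
  }
  A <- standardize_rows(profiles)
  B <- standardize_rows(centroids)
  A %*% t(B) / (ncol(A) - 1)
}

#' k-means clustering of fold-change profiles under correlation similarity
#'
#' Alternates (1) assignment of each gene to the centroid of maximal
#' similarity (Spearman rank correlation by default; ties broken toward
#' the lowest cluster id) and (2) centroid update as the arithmetic mean
#' of member profiles, until assignments stabilise or `max_iterations` is
#' reached. Because the metric is rank-based while centroids are
#' arithmetic means, full-loop convergence is heuristic; the assignment
#' step itself is guaranteed (and asserted every iteration) never to
#' decrease the objective under fixed centroids. Empty clusters are
#' reseeded with the gene worst-fit to its current centroid, so exactly
#' `k` clusters are always returned. Among `restarts` seeded restarts the
#' assignment with the best objective (sum over genes of similarity to
#' the own centroid) is returned; deterministic for a fixed seed.
#'
#' @param mat numeric matrix, genes x stages, with gene rownames.
#' @param k number of clusters (default 8).
#' @param max_iterations iteration cap of the k-means loop (default 1000).
#' @param restarts number of seeded restarts (default 10).
#' @param seed master seed; restart seeds are derived from it.
#' @param metric `"spearman"` (default) or `"pearson"`.
#' @return list of class `cluster_assignment` with `labels` (named
#'   integer vector in 1..k), `centroids` (k x stages matrix),
#'   `objective`, `n_iterations_run`, `metric`.
#' @export
kmeans_correlation <- function(mat, k = 8L, max_iterations = 1000L,
                               restarts = 10L, seed = 1L,
                               metric = c("spearman", "pearson")) {
  metric <- match.arg(metric)
  n <- nrow(mat)
  if (k < 1L || k > n)
    vc_stop("viticre_parameter_error", "k must be between 1 and the number of genes")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(n))
  restart_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, restarts))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr::with_seed(restart_seeds[r],
                            kmeans_single(mat, k, max_iterations, metric))
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best$labels <- setNames(best$labels, rownames(mat))
  colnames(best$centroids) <- colnames(mat)
  structure(best, class = "cluster_assignment")
}

kmeans_single <- function(mat, k, max_iterations, metric) {
  n <- nrow(mat)
  centroids <- mat[sample.int(n, k), , drop = FALSE]
  sim <- similarity_matrix(mat, centroids, metric)
  labels <- max.col(sim, ties.method = "first")
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    # centroid update: arithmetic mean of member profiles
    for (c in seq_len(k)) {
      members <- which(labels == c)
      if (length(members) == 0L) {
        # reseed empty cluster with the worst-fit gene
        own <- sim[cbind(seq_len(n), labels)]
        worst <- which.min(own)
        centroids[c, ] <- mat[worst, ]
        labels[worst] <- c
      } else {
        centroids[c, ] <- colMeans(mat[members, , drop = FALSE])
      }
    }
    sim <- similarity_matrix(mat, centroids, metric)
    obj_before <- sum(sim[cbind(seq_len(n), labels)])
    new_labels <- max.col(sim, ties.method = "first")
    obj_after <- sum(sim[cbind(seq_len(n), new_labels)])
    # assignment step must not decrease the objective under fixed centroids
    if (obj_after < obj_before - 1e-9)
      vc_stop("viticre_internal_error", "assignment step decreased the objective")
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged || iterations >= max_iterations) break
  }
  list(labels = labels, centroids = centroids, objective = obj_after,
       n_iterations_run = iterations, metric = metric)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means (", x$metric, " similarity): ", nrow(x$centroids),
      " clusters, ", length(x$labels), " genes\n", sep = "")
  cat("objective ", format(x$objective, digits = 6), " after ",
      x$n_iterations_run, " iteration(s)\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same gene universe; 1 iff the partitions are identical up to cluster
#' relabeling. Both inputs must be named by gene and cover the same
#' genes.
#'
#' @param labels_a,labels_b named label vectors over the same names.
#' @return the adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      !setequal(names(labels_a), names(labels_b)) ||
      length(labels_a) != length(labels_b))
    vc_stop("viticre_keyed_error", "labelings must cover the same gene universe")
  mclust::adjustedRandIndex(labels_a, labels_b[names(labels_a)])
}
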