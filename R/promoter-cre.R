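# IUPAC degeneracy codes mapped to their base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse-complement nucleotide sequences
#'
#' Standard complement over the full IUPAC alphabet (N maps to N); an
#' involution. Invalid characters are an error.
#'
#' @param x character vector of sequences (IUPAC alphabet).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))),
    error = function(e) vc_stop("viticre_alphabet_error",
                                "invalid character in sequence: ", conditionMessage(e))
  )
  unname(out)
}

#' Extract promoter sequences upstream of each gene's TSS
#'
#' The promoter of a plus-strand gene with TSS at position t (1-based) is
#' the genomic interval \[max(1, t - length), t - 1\] taken as-is; for a
#' minus-strand gene it is \[t + 1, min(L, t + length)\] reverse-
#' complemented, so every returned sequence reads 5'->3' on the gene's own
#' strand toward the TSS. Promoters truncated by a contig edge are
#' retained and flagged `clipped`; genes with zero available upstream
#' sequence are excluded with a message.
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param models gene-model data.frame ([read_gene_models()]).
#' @param length promoter length in bp (default 1000).
#' @return data.frame with columns `gene_id`, `sequence`, `length`,
#'   `clipped`.
#' @export
extract_promoters <- function(genome, models, length = 1000L) {
  if (!is.character(genome)) genome <- setNames(as.character(genome), names(genome))
  missing_contig <- setdiff(unique(models$contig), names(genome))
  if (length(missing_contig))
    vc_stop("viticre_coordinate_error", "contig(s) absent from genome: ",
            paste(missing_contig, collapse = ", "))
  contig_len <- nchar(genome)
  tss <- ifelse(models$strand == "+", models$start, models$end)
  L <- contig_len[models$contig]
  if (any(tss < 1L | tss > L))
    vc_stop("viticre_coordinate_error", "TSS outside contig bounds")
  s <- ifelse(models$strand == "+", pmax(1L, tss - length), tss + 1L)
  e <- ifelse(models$strand == "+", tss - 1L, pmin(L, tss + length))
  ok <- s <= e
  if (any(!ok))
    message("excluding ", sum(!ok), " gene(s) with no upstream sequence: ",
            paste(models$gene_id[!ok], collapse = ", "))
  idx <- which(ok)
  seqs <- substr(genome[models$contig[idx]], s[idx], e[idx])
  minus <- models$strand[idx] == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  data.frame(
    gene_id = models$gene_id[idx],
    sequence = unname(seqs),
    length = e[idx] - s[idx] + 1L,
    clipped = (e[idx] - s[idx] + 1L) < length,
    stringsAsFactors = FALSE
  )
}

# translate an IUPAC pattern into a regular expression; a motif letter
# matches the sequence letter N only when the motif letter is N itself
iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad))
    vc_stop("viticre_format_error", "invalid IUPAC character(s): ",
            paste(unique(chars[bad]), collapse = ", "))
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (ch == "N") set <- c(set, "N")
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# complement an IUPAC pattern and reverse it (pattern-level revcomp)
revcomp_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  chars <- rev(strsplit(pattern, "")[[1L]])
  paste(comp[chars], collapse = "")
}

#' Match an IUPAC motif against sequences
#'
#' TRUE for a sequence iff at least one ungapped window matches the
#' degenerate pattern (R = A/G, Y = C/T, S = C/G, W = A/T, K = G/T,
#' M = A/C, B/D/H/V = three-base sets, N = any base). With
#' `strands = "both"` the reverse complement of the pattern is also
#' scanned on the forward sequence, which is equivalent to scanning the
#' pattern on the reverse strand. An N in the *sequence* satisfies only
#' the motif letter N (conservative: assembly gaps never create matches).
#'
#' @param seqs character vector of sequences (uppercase A/C/G/T/N).
#' @param pattern IUPAC motif string.
#' @param strands `"both"` (default) or `"forward"`.
#' @return logical vector, one element per sequence.
#' @export
iupac_match <- function(seqs, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  hit <- grepl(iupac_to_regex(pattern), seqs, perl = TRUE)
  if (strands == "both")
    hit <- hit | grepl(iupac_to_regex(revcomp_pattern(pattern)), seqs, perl = TRUE)
  hit
}

#' Count promoters containing a motif
#'
#' Presence/absence: multiple occurrences within one promoter count once.
#'
#' @param promoters promoter data.frame ([extract_promoters()]).
#' @param pattern IUPAC motif string.
#' @param strands `"both"` or `"forward"`.
#' @return integer count of promoters with at least one match.
#' @export
count_promoters_with_motif <- function(promoters, pattern,
                                       strands = c("both", "forward")) {
  sum(iupac_match(promoters$sequence, pattern, match.arg(strands)))
}

#' Promoter-by-motif presence/absence matrix
#'
#' @param promoters promoter data.frame.
#' @param library motif library data.frame.
#' @param strands `"both"` or `"forward"`.
#' @return 0/1 integer matrix, rows = genes, columns = motif names.
#' @export
motif_presence_matrix <- function(promoters, library,
                                  strands = c("both", "forward")) {
  strands <- match.arg(strands)
  m <- vapply(library$pattern,
              function(p) as.integer(iupac_match(promoters$sequence, p, strands)),
              integer(nrow(promoters)))
  m <- matrix(m, nrow = nrow(promoters),
              dimnames = list(promoters$gene_id, library$name))
  m
}

#' Promoter CRE overrepresentation per gene cluster
#'
#' For each cluster and each library motif, counts k = cluster promoters
#' containing the motif, n = cluster promoters, K = background promoters
#' containing it, N = background promoters, computes the hypergeometric
#' upper-tail probability P(X >= k), and controls the false discovery
#' rate by Benjamini-Hochberg within each cluster. A motif is flagged
#' enriched when its FDR is below `fdr_threshold` (default 0.01). Cluster
#' genes lacking a promoter are dropped (with a message); clusters empty
#' after that intersection are skipped with a warning.
#'
#' @param cluster_sets named list of gene-id vectors, or a named
#'   gene-to-cluster label vector.
#' @param promoters promoter data.frame for the background universe.
#' @param library motif library data.frame.
#' @param strands `"both"` (default) or `"forward"`.
#' @param fdr_threshold enrichment call threshold on the FDR (default 0.01).
#' @return data.frame with columns `set_id`, `term` (motif name),
#'   `pattern`, `family`, `k`, `n`, `K`, `N`, `p_raw`, `p_adjusted`
#'   (the BH-FDR), `enriched`, sorted by (`set_id`, `p_adjusted`).
#' @export
enrich_motifs <- function(cluster_sets, promoters, library,
                          strands = c("both", "forward"),
                          fdr_threshold = 0.01) {
  strands <- match.arg(strands)
  if (!is.list(cluster_sets)) {
    labs <- cluster_sets[!is.na(cluster_sets)]
    cluster_sets <- split(names(labs), labs)
  }
  presence <- motif_presence_matrix(promoters, library, strands)
  N <- nrow(promoters)
  K <- colSums(presence)
  out <- list()
  for (cl in names(cluster_sets)) {
    genes <- intersect(cluster_sets[[cl]], promoters$gene_id)
    dropped <- length(cluster_sets[[cl]]) - length(genes)
    if (dropped > 0L)
      message("cluster ", cl, ": dropped ", dropped, " gene(s) without promoters")
    if (length(genes) == 0L) {
      warning("cluster ", cl, " empty after promoter intersection; skipped")
      next
    }
    k <- colSums(presence[genes, , drop = FALSE])
    p <- hypergeom_tail(k, n = length(genes), K = K, N = N)
    fdr <- bh_fdr(p)
    out[[cl]] <- data.frame(
      set_id = cl, term = library$name, pattern = library$pattern,
      family = library$family, k = as.integer(k), n = length(genes),
      K = as.integer(K), N = N, p_raw = p, p_adjusted = fdr,
      enriched = fdr < fdr_threshold,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (!length(out))
    return(data.frame(set_id = character(), term = character(),
                      pattern = character(), family = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$set_id, res$p_adjusted, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write planted promoter sequences back into a genome
#'
#' Replaces each gene's promoter interval on the contig with the
#' forward-strand rendering of the given promoter sequence, so that
#' [extract_promoters()] on the patched genome returns exactly these
#' promoters. Used by the simulator to make planted motif instances part
#' of the genome FASTA.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param models gene-model data.frame.
#' @param promoters promoter data.frame whose sequences to write back.
#' @param length promoter length used at extraction.
#' @return named character vector of patched contig sequences.
#' @export
patch_genome_with_promoters <- function(genome, models, promoters, length = 1000L) {
  if (!is.character(genome)) genome <- setNames(as.character(genome), names(genome))
  contig_len <- nchar(genome)
  m <- models[match(promoters$gene_id, models$gene_id), ]
  tss <- ifelse(m$strand == "+", m$start, m$end)
  s <- ifelse(m$strand == "+", pmax(1L, tss - length), tss + 1L)
  e <- ifelse(m$strand == "+", tss - 1L, pmin(contig_len[m$contig], tss + length))
  fwd <- promoters$sequence
  minus <- m$strand == "-"
  if (any(minus)) fwd[minus] <- reverse_complement(fwd[minus])
  # rebuild each contig in one pass: promoter intervals are disjoint by
  # construction, so splice replacements between the untouched gaps
  for (ctg in unique(m$contig)) {
    i <- which(m$contig == ctg)
    i <- i[order(s[i])]
    gaps <- substring(genome[[ctg]], c(1L, e[i] + 1L),
                      c(s[i] - 1L, contig_len[[ctg]]))
    pieces <- character(2L * length(i) + 1L)
    pieces[seq(1L, by = 2L, length.out = length(i) + 1L)] <- gaps
    pieces[seq(2L, by = 2L, length.out = length(i))] <- fwd[i]
    genome[[ctg]] <- paste(pieces, collapse = "")
  }
  genome
}
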