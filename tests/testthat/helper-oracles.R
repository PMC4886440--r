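# Independent oracles and small fixture builders for the test suite.
# These deliberately avoid the package's own implementations.

# -- IUPAC brute force ------------------------------------------------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# all concrete A/C/G/T strings an IUPAC pattern can denote
oracle_expand_iupac <- function(pattern) {
  sets <- ORACLE_IUPAC[strsplit(pattern, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force matcher: expand the degenerate pattern, test fixed substring
# containment on the sequence (and its reverse complement for both strands)
oracle_iupac_match <- function(seqs, pattern, strands = "both") {
  concretes <- oracle_expand_iupac(pattern)
  hit_any <- function(ss) {
    Reduce(`|`, lapply(concretes, function(cc) grepl(cc, ss, fixed = TRUE)),
           init = rep(FALSE, length(ss)))
  }
  hits <- hit_any(seqs)
  if (strands == "both") hits <- hits | hit_any(oracle_revcomp(seqs))
  hits
}

# -- hypergeometric enumeration --------------------------------------------
# upper tail by summing combinatorial counts (exact, independent of phyper)
oracle_hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# -- adjusted Rand index by O(n^2) pair enumeration ------------------------
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa) s10 <- s10 + 1
      else if (sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  2 * (s11 * s00 - s10 * s01) /
    ((s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00))
}

# -- misc -------------------------------------------------------------------
rand_test_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# tiny two-gene genome fixture written to temp FASTA/GFF3
write_tiny_genome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  seq <- rand_test_seqs(1, 5000, seed = 42)
  writeLines(c(">c1 test contig", seq), fa)
  writeLines(c(
    "##gff-version 3",
    "c1\tsim\tgene\t1500\t2500\t.\t+\t.\tID=g1",
    "c1\tsim\tgene\t3500\t4200\t.\t-\t.\tID=g2"
  ), gff)
  list(fasta = fa, gff = gff, seq = seq)
}
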