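#' Read a genome FASTA file
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' header and uppercased. Writing and re-reading a valid file is the
#' identity on sequence content.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) vc_stop("viticre_format_error", "no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) vc_stop("viticre_format_error", "invalid FASTA: ", conditionMessage(e))
  )
  if (length(seqs) == 0L)
    vc_stop("viticre_format_error", "empty FASTA file: ", path)
  if (any(Biostrings::width(seqs) == 0L))
    vc_stop("viticre_format_error", "FASTA record with empty sequence in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a genome FASTA file
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Retains only features of `feature_type` (default `gene`); coordinates are
#' kept 1-based inclusive as in GFF3. If `exon` features carrying a `Parent`
#' attribute are present, a gene's exonic length is the total width of its
#' reduced exons; otherwise it defaults to the gene span. Malformed records
#' are rejected, never repaired: unknown strand and duplicate gene IDs are
#' format errors.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type to retain (default `"gene"`).
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `exonic_length`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  if (!file.exists(path)) vc_stop("viticre_format_error", "no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) vc_stop("viticre_format_error", "invalid GFF3: ", conditionMessage(e))
  )
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(genes) == 0L)
    vc_stop("viticre_format_error", "no '", feature_type, "' features in ", path)
  strand <- as.character(BiocGenerics::strand(genes))
  if (any(!strand %in% c("+", "-")))
    vc_stop("viticre_format_error", "feature with unknown strand symbol (need + or -)")
  ids <- as.character(genes$ID)
  if (any(is.na(ids)) || any(ids == ""))
    vc_stop("viticre_format_error", "gene feature without ID attribute")
  if (anyDuplicated(ids))
    vc_stop("viticre_format_error", "duplicate gene ID(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  exonic <- setNames(BiocGenerics::width(genes), ids)
  exons <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(exons) > 0L && !is.null(exons$Parent)) {
    parent <- vapply(as.list(exons$Parent),
                     function(p) if (length(p)) p[[1L]] else NA_character_,
                     character(1))
    keep <- !is.na(parent) & parent %in% ids
    if (any(keep)) {
      byg <- split(IRanges::ranges(exons[keep]), parent[keep])
      lens <- vapply(byg, function(r) sum(BiocGenerics::width(IRanges::reduce(r))), integer(1))
      exonic[names(lens)] <- lens
    }
  }
  data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(genes)),
    start = BiocGenerics::start(genes),
    end = BiocGenerics::end(genes),
    strand = strand,
    exonic_length = as.integer(exonic[ids]),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per model with an `ID` attribute, 1-based
#' inclusive coordinates.
#'
#' @param models data.frame as returned by [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$contig,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand
  )
  gr$type <- "gene"
  gr$ID <- models$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Read a library of IUPAC cis-regulatory element motifs
#'
#' Expects a TSV with columns `name`, `pattern`, `family`, `source`.
#' Patterns must be non-empty uppercase strings over the IUPAC nucleotide
#' alphabet (A, C, G, T plus the degeneracy codes R, Y, S, W, K, M, B, D,
#' H, V, N). The package ships such a library of PLACE/PBM-curated plant
#' transcription-factor binding motifs at
#' `system.file("extdata", "cre_motifs.tsv", package = "viticre")`.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `name`, `pattern`, `family`, `source`.
#' @export
read_motif_library <- function(path) {
  if (!file.exists(path)) vc_stop("viticre_format_error", "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("name", "pattern", "family", "source")
  if (nrow(df) == 0L) {
    warning("empty motif library: ", path)
    return(data.frame(name = character(), pattern = character(),
                      family = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(need %in% names(df)))
    vc_stop("viticre_format_error", "motif TSV must have columns ",
            paste(need, collapse = ", "))
  df <- df[, need]
  bad <- !vapply(df$pattern, function(p) {
    nzchar(p) && all(strsplit(p, "")[[1]] %in% IUPAC_LETTERS)
  }, logical(1))
  if (any(bad))
    vc_stop("viticre_format_error", "invalid IUPAC pattern(s): ",
            paste(df$pattern[bad], collapse = ", "))
  if (anyDuplicated(df$name))
    vc_stop("viticre_format_error", "duplicate motif name(s)")
  df
}

#' The packaged CRE motif library
#'
#' Convenience loader for the PLACE/PBM-derived motif fixture shipped with
#' the package (22 degenerate IUPAC motifs from bZIP/ABRE, bHLH, AP2/ERF,
#' MYB, NAC, MADS-box, ARF, WRKY, TCP, E2F and light-response families).
#'
#' @return data.frame as from [read_motif_library()].
#' @export
packaged_motif_library <- function() {
  read_motif_library(system.file("extdata", "cre_motifs.tsv", package = "viticre"))
}

#' Write an enrichment result table
#'
#' TSV columns: `set_id`, `term`, `matches_in_sample`, `sample_size`,
#' `matches_in_background`, `background_size`, `p_raw`, `p_adjusted`,
#' `enriched`; rows sorted by (`set_id`, `p_adjusted`). An empty result
#' list yields a header-only file.
#'
#' @param results data.frame with columns `set_id`, `term`, `k`, `n`, `K`,
#'   `N`, `p_raw`, `p_adjusted`, `enriched` (as produced by
#'   [enrich_bins()] or [enrich_motifs()]).
#' @param path output path.
#' @export
write_enrichment_table <- function(results, path) {
  out <- data.frame(
    set_id = results$set_id %||% character(),
    term = results$term %||% character(),
    matches_in_sample = results$k %||% integer(),
    sample_size = results$n %||% integer(),
    matches_in_background = results$K %||% integer(),
    background_size = results$N %||% integer(),
    p_raw = results$p_raw %||% numeric(),
    p_adjusted = results$p_adjusted %||% numeric(),
    enriched = results$enriched %||% logical(),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$set_id, out$p_adjusted), , drop = FALSE]
  write_tsv(out, path)
}

#' Read back an enrichment result table
#' @param path path written by [write_enrichment_table()].
#' @return data.frame in the schema of [enrich_bins()] results.
#' @export
read_enrichment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = c(set_id = "character", term = "character"))
  data.frame(
    set_id = df$set_id, term = df$term,
    k = df$matches_in_sample, n = df$sample_size,
    K = df$matches_in_background, N = df$background_size,
    p_raw = df$p_raw, p_adjusted = df$p_adjusted,
    enriched = df$enriched, stringsAsFactors = FALSE
  )
}

# tab-separated, "." for missing, no quoting; full double precision
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, vapply(x, function(v) format(v, digits = 17, scientific = NA), character(1)))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write / read a count matrix TSV
#'
#' Gene-by-sample integer counts; the header encodes sample identity as
#' `size_stage_rep` (e.g. `small_47_1`), and the first column is `gene_id`.
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @return for the reader, an integer matrix.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  if (any(m < 0)) vc_stop("viticre_format_error", "negative counts in ", path)
  parse_sample_ids(colnames(m))  # validates header encoding
  m
}

#' Decode `size_stage_rep` sample identifiers
#'
#' @param ids character vector like `"small_47_1"`.
#' @return data.frame with columns `sample`, `size`, `stage`, `rep`.
#' @export
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    vc_stop("viticre_format_error", "sample id(s) not in size_stage_rep form: ",
            paste(ids[bad], collapse = ", "))
  size <- vapply(parts, `[`, "", 1L)
  stage <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  rep <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (any(!size %in% BERRY_SIZES) || anyNA(stage) || anyNA(rep))
    vc_stop("viticre_format_error", "malformed sample id(s)")
  if (anyDuplicated(data.frame(size, stage, rep)))
    vc_stop("viticre_format_error", "duplicate (size, stage, rep) sample triples")
  data.frame(sample = ids, size = size, stage = stage, rep = rep,
             stringsAsFactors = FALSE)
}

#' Write / read a differential-expression table
#'
#' Columns `gene`, `stage`, `log2fc` (small/large, log2 units), `fdr`.
#'
#' @param de data.frame with those columns.
#' @param path file path.
#' @export
write_de_table <- function(de, path) write_tsv(de[, c("gene", "stage", "log2fc", "fdr")], path)

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "stage", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    vc_stop("viticre_format_error", "DE table needs columns ", paste(need, collapse = ", "))
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    vc_stop("viticre_format_error", "fdr outside [0, 1]")
  if (anyDuplicated(df[, c("gene", "stage")]))
    vc_stop("viticre_format_error", "duplicate (gene, stage) rows")
  df[, need]
}

#' Write / read a gene-to-BIN annotation table
#'
#' Columns `gene_id`, `bin_code`; BIN codes are dot-separated numeric
#' strings (e.g. `16.8`).
#'
#' @param bins data.frame with columns `gene_id`, `bin_code`.
#' @param path file path.
#' @export
write_bin_annotation <- function(bins, path) write_tsv(bins[, c("gene_id", "bin_code")], path)

#' @rdname write_bin_annotation
#' @export
read_bin_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = c(bin_code = "character"))
  if (!all(c("gene_id", "bin_code") %in% names(df)))
    vc_stop("viticre_format_error", "BIN table needs columns gene_id, bin_code")
  validate_bin_codes(df$bin_code)
  df[, c("gene_id", "bin_code")]
}

validate_bin_codes <- function(codes) {
  bad <- !grepl("^[0-9]+(\\.[0-9]+)*$", codes)
  if (any(bad))
    vc_stop("viticre_annotation_error", "malformed BIN code(s): ",
            paste(unique(codes[bad]), collapse = ", "))
  invisible(codes)
}
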