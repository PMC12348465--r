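# Readers and writers for the plain-text formats the pipeline exchanges:
# expression matrices and sample sheets (TSV), gene lengths, variant tables,
# FASTA (via Biostrings), target/guide configs (YAML), BED6.

#' Read a gene x sample expression matrix from TSV
#'
#' First column is the gene identifier, header row holds sample identifiers.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression matrix needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stopf("duplicated gene ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE)) stopf("negative expression values in %s", path)
  m
}

#' Read a sample sheet (sample_id, tissue, stage)
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `tissue` and optionally `stage`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("sample sheet missing column(s): %s",
                              paste(miss, collapse = ", "))
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  df
}

#' Read gene lengths from a two-column TSV (gene_id, length_bp)
#' @param path Path to a TSV file.
#' @return Named integer vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lens <- as.numeric(df[[2]])
  names(lens) <- as.character(df[[1]])
  if (any(lens <= 0 | !is.finite(lens))) stopf("gene lengths must be positive")
  lens
}

#' Read an amplicon variant read-count table
#'
#' Expects the per-target output shape of high-throughput amplicon genotyping
#' platforms: one row per observed read variant with columns `line_id`,
#' `locus_id`, `variant_seq`, `read_count`.
#'
#' @param path Path to a TSV file.
#' @return data.frame with the four required columns.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "locus_id", "variant_seq", "read_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stopf("variant table missing column(s): %s",
                              paste(miss, collapse = ", "))
  df$variant_seq <- check_dna(df$variant_seq, "variant_seq")
  if (any(df$read_count < 0)) stopf("read_count must be >= 0")
  df
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' Write named sequences to a FASTA file
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read target (amplicon + spacer) specifications from YAML
#'
#' The YAML file holds a list `targets:`, each entry with fields `locus_id`,
#' `reference_amplicon` (or `amplicon_id` referring to a FASTA), `spacer`,
#' `pam`, `protospacer_start`, `spacer_strand`.
#'
#' @param path YAML file path.
#' @param amplicons Optional named character vector of amplicon sequences
#'   used to resolve `amplicon_id` references.
#' @return List of [target_spec()] objects.
#' @export
read_targets_yaml <- function(path, amplicons = NULL) {
  y <- yaml::read_yaml(path)
  entries <- y$targets %||% y
  lapply(entries, function(e) {
    ref <- e$reference_amplicon
    if (is.null(ref) && !is.null(e$amplicon_id)) {
      if (is.null(amplicons) || !e$amplicon_id %in% names(amplicons)) {
        stopf("amplicon '%s' not found in supplied FASTA", e$amplicon_id)
      }
      ref <- amplicons[[e$amplicon_id]]
    }
    target_spec(locus_id = e$locus_id,
                reference_amplicon = ref,
                spacer = e$spacer,
                pam = e$pam %||% "NGG",
                protospacer_start = e$protospacer_start,
                spacer_strand = e$spacer_strand %||% "+")
  })
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive hit coordinates to BED6 and optionally write
#'
#' @param df data.frame with columns naming the sequence, `start`, `end`
#'   (1-based inclusive), a name column and `strand`.
#' @param seq_col,name_col,score Column names / constant score used to fill
#'   the BED fields.
#' @param path Optional output path; when given the BED text is written there.
#' @return data.frame in BED6 column order (0-based half-open), invisibly
#'   when written to a file.
#' @export
to_bed6 <- function(df, seq_col = "seq_id", name_col = "name", score = 0,
                    path = NULL) {
  bed <- data.frame(
    chrom = df[[seq_col]],
    chromStart = df$start - 1L,
    chromEnd = df$end,
    name = df[[name_col]],
    score = score,
    strand = df$strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
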