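# Cis-regulatory element scanning of promoter sequences against an IUPAC
# consensus catalog (a local analogue of PLACE/PlantCARE lookups).

#' Build a motif catalog
#'
#' @param name Unique element names.
#' @param pattern IUPAC consensus strings.
#' @param category One of `core`, `light`, `hormone`, `stress` per entry.
#' @return data.frame of class `motif_catalog`.
#' @export
motif_catalog <- function(name, pattern, category) {
  if (anyDuplicated(name)) stopf("catalog names must be unique")
  if (any(nchar(pattern) == 0)) stopf("catalog patterns must be non-empty")
  pattern <- vapply(pattern, check_iupac, character(1), USE.NAMES = FALSE)
  ok <- c("core", "light", "hormone", "stress")
  if (!all(category %in% ok)) {
    stopf("categories must be one of: %s", paste(ok, collapse = ", "))
  }
  structure(data.frame(name = name, pattern = pattern, category = category,
                       stringsAsFactors = FALSE),
            class = c("motif_catalog", "data.frame"))
}

#' Read a motif catalog from TSV (name, pattern, category)
#' @param path TSV path.
#' @return A [motif_catalog()].
#' @export
read_motif_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  motif_catalog(df$name, df$pattern, df$category)
}

#' The default plant cis-element catalog
#'
#' Published PLACE/PlantCARE consensus strings for the core transcription
#' elements (TATA-box, CAAT-box), light-responsive elements (Box 4,
#' GATA-motif, AT1-motif), hormone-responsive elements (ABRE, TGACG-motif,
#' TCA-element, P-box) and stress-responsive elements (as-1, ARE, WUN-motif,
#' TC-rich repeats, STRE). Shipped as an editable TSV in `extdata`.
#'
#' @return A [motif_catalog()].
#' @export
default_motif_catalog <- function() {
  read_motif_catalog(system.file("extdata", "plantcare_catalog.tsv",
                                 package = "calluscope", mustWork = TRUE))
}

#' All match positions of an IUPAC pattern in a DNA sequence
#'
#' Overlapping matches are all reported. An `N` in the sequence matches no
#' pattern symbol (conservative: ambiguous sequence never produces a hit),
#' while an `N` in the pattern matches any of A/C/G/T.
#'
#' @param pattern IUPAC consensus string.
#' @param seq DNA string over A/C/G/T/N.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @examples
#' iupac_matches("WTTSSS", "ATTGCC")  # 1
#' @export
iupac_matches <- function(pattern, seq) {
  seq <- check_dna(seq, "seq")
  rx <- iupac_to_regex(pattern)
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m)
}

#' Scan one promoter sequence against a motif catalog
#'
#' Both strands are scanned; minus-strand hits are reported in forward-strand
#' coordinates (1-based inclusive), with `matched_seq` holding the
#' forward-strand bases at the hit (reverse-complement it to see the motif).
#'
#' @param seq Promoter DNA string.
#' @param catalog A [motif_catalog()].
#' @param promoter_id Identifier attached to the hits.
#' @return data.frame (promoter_id, motif_name, category, strand, start, end,
#'   matched_seq) sorted by (start, motif_name).
#' @export
scan_promoter <- function(seq, catalog, promoter_id = "promoter") {
  if (nrow(catalog) == 0) stopf("catalog is empty")
  if (nchar(seq) == 0) {
    return(data.frame(promoter_id = character(0), motif_name = character(0),
                      category = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      matched_seq = character(0), stringsAsFactors = FALSE))
  }
  seq <- check_dna(seq, "promoter")
  L <- nchar(seq)
  rc <- revcomp(seq)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    pat <- catalog$pattern[i]
    k <- nchar(pat)
    fwd <- iupac_matches(pat, seq)
    rev_ <- iupac_matches(pat, rc)
    out <- list()
    if (length(fwd) > 0) {
      out$f <- data.frame(promoter_id = promoter_id,
                          motif_name = catalog$name[i],
                          category = catalog$category[i],
                          strand = "+", start = fwd, end = fwd + k - 1L,
                          matched_seq = substring(seq, fwd, fwd + k - 1L),
                          stringsAsFactors = FALSE)
    }
    if (length(rev_) > 0) {
      start_f <- L - (rev_ + k - 1L) + 1L
      out$r <- data.frame(promoter_id = promoter_id,
                          motif_name = catalog$name[i],
                          category = catalog$category[i],
                          strand = "-", start = start_f,
                          end = start_f + k - 1L,
                          matched_seq = substring(seq, start_f, start_f + k - 1L),
                          stringsAsFactors = FALSE)
    }
    if (length(out) == 0) NULL else do.call(rbind, out)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    return(scan_promoter("", catalog, promoter_id))
  }
  hits <- hits[order(hits$start, hits$motif_name, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of promoters
#' @param seqs Named character vector of promoter sequences.
#' @param catalog A [motif_catalog()].
#' @return Row-bound hit table from [scan_promoter()].
#' @export
scan_promoters <- function(seqs, catalog) {
  if (is.null(names(seqs))) names(seqs) <- paste0("promoter_", seq_along(seqs))
  do.call(rbind, lapply(names(seqs), function(id) {
    scan_promoter(seqs[[id]], catalog, promoter_id = id)
  }))
}

#' Per-promoter, per-category element counts
#'
#' @param hits Hit table from [scan_promoter()]/[scan_promoters()].
#' @param promoter_ids Promoters to include (rows of all zero when a promoter
#'   has no hits); defaults to those present in `hits`.
#' @param categories Category columns; defaults to the standard four.
#' @return data.frame, one row per promoter with one count column per
#'   category plus `total`.
#' @export
summarize_elements <- function(hits, promoter_ids = NULL,
                               categories = c("core", "light", "hormone", "stress")) {
  promoter_ids <- promoter_ids %||% unique(hits$promoter_id)
  counts <- matrix(0L, nrow = length(promoter_ids), ncol = length(categories),
                   dimnames = list(promoter_ids, categories))
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$promoter_id, levels = promoter_ids),
                 factor(hits$category, levels = categories))
    counts <- counts + unclass(tab)
  }
  out <- data.frame(promoter_id = promoter_ids, counts,
                    total = rowSums(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Extract promoter regions upstream of gene start codons
#'
#' Takes the `length` bases immediately 5' of the start-codon coordinate on
#' the gene's strand (clipped at the sequence boundary): for a `+`-strand
#' gene positions `start - length .. start - 1`, for a `-`-strand gene the
#' reverse complement of `start + 1 .. start + length`.
#'
#' @param genome Named character vector of chromosome/contig sequences.
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`
#'   (1-based start-codon position) and `strand`.
#' @param length Promoter length in bp (default 2000).
#' @return Named character vector of promoter sequences.
#' @export
extract_promoters <- function(genome, genes, length = 2000) {
  vapply(seq_len(nrow(genes)), function(i) {
    chrom <- genome[[genes$seq_id[i]]]
    if (is.null(chrom)) stopf("sequence '%s' not in genome", genes$seq_id[i])
    pos <- genes$start[i]
    if (genes$strand[i] == "+") {
      from <- max(1L, pos - length)
      substring(chrom, from, pos - 1L)
    } else {
      to <- min(nchar(chrom), pos + length)
      revcomp(substring(chrom, pos + 1L, to))
    }
  }, character(1)) |>
    stats::setNames(genes$gene_id)
}
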