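# Shared low-level helpers: IUPAC nucleotide algebra, reverse complement,
# rounding, small input-checking utilities.

#' IUPAC nucleotide code expansions
#'
#' Named list mapping each IUPAC nucleotide code to the set of unambiguous
#' bases it stands for. `N` expands to all four bases; an `N` in a *subject*
#' sequence is never treated as matching (see [iupac_matches()]).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement. Handles the full IUPAC alphabet (ambiguity
#' codes are complemented to their partner codes).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' revcomp("TGACG")  # "CGTCA"
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), halves are rounded away from zero:
#' `round_half_up(12.5, 0)` is 13, `round_half_up(-12.5, 0)` is -13. This is
#' the convention used for the cohort percentage tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), toupper(x))
  if (any(bad)) {
    stopf("%s contains non-DNA characters (allowed: %s): %s",
          what, alphabet, substr(toupper(x[bad][1]), 1, 40))
  }
  toupper(x)
}

check_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stopf("invalid IUPAC code(s) in pattern '%s': %s",
          pattern, paste(unique(bad), collapse = ", "))
  }
  pattern
}

# Translate an IUPAC pattern into a regular expression over {A,C,G,T}.
# N in the *pattern* matches any base; N in the subject matches nothing
# because the classes never include the letter N.
iupac_to_regex <- function(pattern) {
  pattern <- check_iupac(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_CODES[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Does each 3-mer (or k-mer) match an IUPAC pattern of the same length?
iupac_kmer_match <- function(kmers, pattern) {
  grepl(paste0("^", iupac_to_regex(pattern), "$"), kmers)
}
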