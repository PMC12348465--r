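# Shared fixtures and independent oracles used across the test files.
# Everything here is built in code; no files are read.

# A small editing target with a known protospacer: position 5 of the
# protospacer is a C (so the canonical C->T edit is well-defined).
fixture_target <- function() {
  spacer <- "GATTCCAGTACGGCTAGTCA"
  left <- "ATGGCGTTAACCGGATCCTT"
  right <- "CCGGAATTCAGGCTTAAGGC"
  amp <- paste0(left, spacer, "TGG", right)
  target_spec("locusA", amp, spacer, pam = "NGG",
              protospacer_start = nchar(left) + 1L, spacer_strand = "+")
}

# Substitute the base at protospacer position `pos` of the fixture amplicon.
fixture_substituted <- function(target, pos, alt) {
  apos <- target$protospacer_start + pos - 1L
  ref <- target$reference_amplicon
  paste0(substring(ref, 1, apos - 1L), alt,
         substring(ref, apos + 1L, nchar(ref)))
}

# Delete one base at protospacer position `pos`.
fixture_deleted <- function(target, pos) {
  apos <- target$protospacer_start + pos - 1L
  ref <- target$reference_amplicon
  paste0(substring(ref, 1, apos - 1L), substring(ref, apos + 1L, nchar(ref)))
}

# Independent brute-force IUPAC matcher: slide a window and test every
# pattern symbol's base set by direct lookup (no regex involved).
oracle_iupac_matches <- function(pattern, seq) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  k <- length(p)
  if (length(s) < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(length(s) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% sets[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Independent brute-force off-target scan: every window of every position on
# both strands, PAM checked by membership in the explicitly enumerated PAM
# string set, Hamming distance counted base by base.
oracle_offtarget_scan <- function(sequences, spacer, max_mm = 4,
                                  pams = c("NGG", "NAG")) {
  bases <- c("A", "C", "G", "T")
  pam_set <- unlist(lapply(pams, function(p) {
    stopifnot(substring(p, 1, 1) == "N")
    paste0(bases, substring(p, 2))
  }))
  spacer_chars <- strsplit(spacer, "")[[1]]
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  out <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else rc(s)
      if (L < 23) next
      for (p in seq_len(L - 22)) {
        pam <- substring(ss, p + 20, p + 22)
        if (!pam %in% pam_set) next
        cand <- strsplit(substring(ss, p, p + 19), "")[[1]]
        d <- sum(cand != spacer_chars)
        if (d > max_mm || any(!cand %in% bases)) next
        start_f <- if (strand == "+") p else L - (p + 19) + 1
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, start = start_f, end = start_f + 19L,
          strand = strand, n_mismatches = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatches = integer(0)))
  }
  do.call(rbind, out)
}

site_key <- function(df) sort(paste(df$seq_id, df$strand, df$start, df$n_mismatches))

# Printed per-construct editing statistics of the six evaluated constructs
# (counts and the three percentage columns).
published_rates <- function() {
  cbind(published_cohort_counts(),
        data.frame(editing_efficiency = c(14.3, 21.4, 14.3, 7.1, 20.8, 28.6),
                   homozygous_rate = c(7.1, 7.1, 14.3, 0.0, 12.5, 10.7),
                   indel_rate = c(7.1, 10.7, 7.1, 7.1, 12.5, 10.7)))
}
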