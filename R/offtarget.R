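# sgRNA off-target enumeration and ranking: every 20-mer 5' of a PAM match,
# on either strand, within a Hamming-distance budget of the spacer.

#' Define a guide for off-target scanning
#'
#' @param spacer 20-nt spacer sequence.
#' @param pam_patterns IUPAC PAM patterns accepted 3' of a candidate
#'   protospacer (default `c("NGG", "NAG")`, the SpCas9 tolerance).
#' @param max_mismatches Maximum Hamming distance to the spacer (default 4).
#' @return List of class `guide_spec`.
#' @export
guide_spec <- function(spacer, pam_patterns = c("NGG", "NAG"),
                       max_mismatches = 4) {
  spacer <- check_dna(spacer, "spacer", allow_n = FALSE)
  if (nchar(spacer) != 20) stopf("spacer must be 20 nt")
  if (max_mismatches < 0) stopf("max_mismatches must be >= 0")
  pam_patterns <- vapply(pam_patterns, check_iupac, character(1),
                         USE.NAMES = FALSE)
  structure(list(spacer = spacer, pam_patterns = pam_patterns,
                 max_mismatches = as.integer(max_mismatches)),
            class = "guide_spec")
}

#' Default per-position mismatch penalty weights
#'
#' PAM-proximal mismatches (protospacer positions 13-20, the seed region)
#' are penalised more heavily (0.3) than PAM-distal ones (positions 1-12,
#' 0.1). Position 1 is the PAM-distal end.
#'
#' @return Numeric vector of length 20 in \[0, 1\].
#' @export
default_mismatch_weights <- function() {
  c(rep(0.1, 12), rep(0.3, 8))
}

# Candidate scan of one strand of one sequence (already oriented so the
# protospacer reads 5'->3' with the PAM 3' of it). Returns 1-based start
# positions on the scanned orientation plus mismatch counts and PAM strings.
scan_oriented <- function(seq, guide) {
  L <- nchar(seq)
  k <- 20L
  pam_len <- nchar(guide$pam_patterns[1])
  if (any(nchar(guide$pam_patterns) != pam_len)) {
    stopf("all PAM patterns must have equal length")
  }
  if (L < k + pam_len) return(NULL)
  pam_rx <- paste0("(?=(", paste(vapply(guide$pam_patterns, iupac_to_regex,
                                        character(1)), collapse = "|"), "))")
  m <- gregexpr(pam_rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  pam_pos <- as.integer(m)
  pam_pos <- pam_pos[pam_pos > k & pam_pos + pam_len - 1L <= L]
  if (length(pam_pos) == 0) return(NULL)
  starts <- pam_pos - k
  cand <- substring(seq, starts, starts + k - 1L)
  spacer_chars <- strsplit(guide$spacer, "", fixed = TRUE)[[1]]
  mm <- matrix(FALSE, nrow = length(cand), ncol = k)
  for (i in seq_len(k)) {
    mm[, i] <- substring(cand, i, i) != spacer_chars[i]
  }
  n_mm <- rowSums(mm)
  keep <- n_mm <= guide$max_mismatches & !grepl("N", cand, fixed = TRUE)
  if (!any(keep)) return(NULL)
  list(start = starts[keep],
       site_seq = cand[keep],
       pam_seq = substring(seq, pam_pos[keep], pam_pos[keep] + pam_len - 1L),
       n_mismatches = as.integer(n_mm[keep]),
       mismatch_positions = apply(mm[keep, , drop = FALSE], 1, which,
                                  simplify = FALSE))
}

#' Enumerate candidate off-target sites
#'
#' Scans both strands of every input sequence for 20-mers 5'-adjacent to a
#' PAM match with Hamming distance at most `max_mismatches` to the spacer.
#' Each qualifying site is reported exactly once; the on-target site appears
#' with `n_mismatches = 0`. Coordinates are 1-based inclusive on the forward
#' strand and cover the protospacer (PAM excluded). Sequences shorter than
#' protospacer + PAM are skipped with a message.
#'
#' @param sequences Named character vector (genome or sequence panel).
#' @param guide A [guide_spec()].
#' @param weights Per-position mismatch penalties used to score each site
#'   (see [score_site()]).
#' @return data.frame (seq_id, start, end, strand, site_seq, pam_seq,
#'   n_mismatches, mismatch_positions, score) sorted by decreasing score.
#' @export
enumerate_sites <- function(sequences, guide,
                            weights = default_mismatch_weights()) {
  if (length(sequences) == 0) stopf("no sequences supplied")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq_", seq_along(sequences))
  }
  pam_len <- nchar(guide$pam_patterns[1])
  rows <- list()
  for (id in names(sequences)) {
    s <- check_dna(sequences[[id]], sprintf("sequence '%s'", id))
    L <- nchar(s)
    if (L < 20L + pam_len) {
      message(sprintf("skipping '%s': shorter than protospacer + PAM", id))
      next
    }
    fw <- scan_oriented(s, guide)
    if (!is.null(fw)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = fw$start, end = fw$start + 19L, strand = "+",
        site_seq = fw$site_seq, pam_seq = fw$pam_seq,
        n_mismatches = fw$n_mismatches,
        mismatch_positions = vapply(fw$mismatch_positions, paste,
                                    character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
    rv <- scan_oriented(revcomp(s), guide)
    if (!is.null(rv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = L - (rv$start + 19L) + 1L,
        end = L - rv$start + 1L, strand = "-",
        site_seq = rv$site_seq, pam_seq = rv$pam_seq,
        n_mismatches = rv$n_mismatches,
        mismatch_positions = vapply(rv$mismatch_positions, paste,
                                    character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_seq = character(0), pam_seq = character(0),
                      n_mismatches = integer(0),
                      mismatch_positions = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, rows)
  sites <- sites[!duplicated(sites[, c("seq_id", "strand", "start")]), ,
                 drop = FALSE]
  sites$score <- vapply(seq_len(nrow(sites)), function(i) {
    score_site(guide$spacer, sites[i, ], weights)
  }, numeric(1))
  sites <- sites[order(-sites$score, sites$n_mismatches, sites$seq_id,
                       sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Score an off-target site
#'
#' Multiplicative per-position penalties: the score is the product over
#' mismatched positions of `1 - weight[p]` (protospacer coordinates,
#' position 1 = PAM-distal). A perfect match scores 1; every added mismatch
#' with a positive weight strictly decreases the score. Sites whose PAM is
#' NAG rather than NGG are additionally multiplied by 0.5.
#'
#' @param spacer 20-nt spacer.
#' @param site One-row data.frame (or list) with `site_seq` and `pam_seq`
#'   fields, as produced by [enumerate_sites()].
#' @param weights Numeric vector of length 20 with entries in \[0, 1\].
#' @param nag_multiplier Penalty multiplier for NAG PAMs (default 0.5).
#' @return Score in \[0, 1\].
#' @export
score_site <- function(spacer, site, weights = default_mismatch_weights(),
                       nag_multiplier = 0.5) {
  if (length(weights) != nchar(spacer)) {
    stopf("weights length (%d) must equal spacer length (%d)",
          length(weights), nchar(spacer))
  }
  if (any(weights < 0 | weights > 1)) stopf("weights must lie in [0, 1]")
  site_seq <- site$site_seq
  if (nchar(site_seq) != nchar(spacer)) {
    stopf("site length (%d) must equal spacer length (%d)",
          nchar(site_seq), nchar(spacer))
  }
  a <- strsplit(spacer, "", fixed = TRUE)[[1]]
  b <- strsplit(site_seq, "", fixed = TRUE)[[1]]
  mm <- which(a != b)
  score <- prod(1 - weights[mm])
  pam <- site$pam_seq %||% NA_character_
  if (!is.na(pam) && nchar(pam) == 3 &&
        substring(pam, 2, 3) == "AG") {
    score <- score * nag_multiplier
  }
  score
}

#' Rank off-target sites and keep the top k
#'
#' Descending by score, ties broken by fewer mismatches, then sequence id,
#' then start. The on-target site (0 mismatches) is excluded by default.
#'
#' @param sites data.frame from [enumerate_sites()].
#' @param k Number of sites to keep (default 3).
#' @param exclude_on_target Drop 0-mismatch sites first (default TRUE).
#' @return The top-k rows.
#' @export
rank_sites <- function(sites, k = 3, exclude_on_target = TRUE) {
  if (k < 1) stopf("k must be >= 1")
  if (exclude_on_target) {
    sites <- sites[sites$n_mismatches > 0, , drop = FALSE]
  }
  o <- order(-sites$score, sites$n_mismatches, sites$seq_id, sites$start)
  out <- sites[utils::head(o, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
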