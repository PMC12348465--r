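# Amplicon genotyping of base-editing outcomes: per-variant classification by
# global alignment, the 1% read filter, cumulative per-locus mutation
# frequency, zygosity calls, per-line calls and cohort editing statistics.

#' Zygosity classification thresholds
#'
#' A locus is called homozygous when the cumulative mutation frequency
#' exceeds 0.90 (strict), heterozygous between 0.20 and 0.90 (inclusive),
#' chimeric below 0.20, and wildtype at exactly 0.
#' @keywords internal
ZYGOSITY_HOMOZYGOUS <- 0.90
ZYGOSITY_HETEROZYGOUS <- 0.20

#' Define an editing target (amplicon + protospacer)
#'
#' @param locus_id Locus identifier (e.g. `"AhALS2-A"`).
#' @param reference_amplicon Wildtype amplicon sequence.
#' @param spacer 20-nt spacer sequence (protospacer-strand orientation).
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer
#'   (default `"NGG"`).
#' @param protospacer_start 1-based amplicon position of spacer base 1 (the
#'   PAM-distal base).
#' @param spacer_strand `"+"` if the protospacer reads along the amplicon
#'   forward strand, `"-"` otherwise.
#' @return List of class `target_spec`.
#' @export
target_spec <- function(locus_id, reference_amplicon, spacer, pam = "NGG",
                        protospacer_start, spacer_strand = c("+", "-")) {
  spacer_strand <- match.arg(spacer_strand)
  reference_amplicon <- check_dna(reference_amplicon, "reference_amplicon",
                                  allow_n = FALSE)
  spacer <- check_dna(spacer, "spacer", allow_n = FALSE)
  if (nchar(spacer) != 20) stopf("spacer must be 20 nt")
  pam <- check_iupac(pam)
  k <- nchar(spacer)
  L <- nchar(reference_amplicon)
  if (spacer_strand == "+") {
    proto <- substring(reference_amplicon, protospacer_start,
                       protospacer_start + k - 1L)
    pam_seq <- substring(reference_amplicon, protospacer_start + k,
                         protospacer_start + k + nchar(pam) - 1L)
  } else {
    if (protospacer_start - k + 1L - nchar(pam) < 1L) {
      stopf("protospacer/PAM extends past the amplicon 5' end")
    }
    proto <- revcomp(substring(reference_amplicon, protospacer_start - k + 1L,
                               protospacer_start))
    pam_seq <- revcomp(substring(reference_amplicon,
                                 protospacer_start - k - nchar(pam) + 1L,
                                 protospacer_start - k))
  }
  if (!identical(proto, spacer)) {
    stopf("spacer does not occur at position %d (%s strand) of amplicon '%s'",
          protospacer_start, spacer_strand, locus_id)
  }
  if (!iupac_kmer_match(pam_seq, pam)) {
    stopf("PAM '%s' 3' of the protospacer does not match pattern '%s'",
          pam_seq, pam)
  }
  structure(list(locus_id = locus_id,
                 reference_amplicon = reference_amplicon,
                 spacer = spacer, pam = pam,
                 protospacer_start = as.integer(protospacer_start),
                 spacer_strand = spacer_strand,
                 amplicon_length = L),
            class = "target_spec")
}

# Map a 1-based amplicon coordinate to a protospacer coordinate
# (position 1 = PAM-distal base). Returns NA outside the protospacer.
amplicon_to_protospacer <- function(target, pos) {
  ps <- if (target$spacer_strand == "+") {
    pos - target$protospacer_start + 1L
  } else {
    target$protospacer_start - pos + 1L
  }
  ps[ps < 1L | ps > 20L] <- NA_integer_
  ps
}

#' Exclude read variants below a frequency threshold
#'
#' Raw frequencies are computed over the pre-filter read total; variants
#' strictly below `min_freq` (default 1%) are removed — a variant at exactly
#' the threshold is retained. Frequencies of the survivors are then
#' recomputed over the retained total (set `renormalize = FALSE` to keep the
#' pre-filter denominator). The filter is idempotent: survivors' frequencies
#' can only grow after renormalisation.
#'
#' @param variants data.frame with at least a `read_count` column.
#' @param min_freq Exclusion threshold on the raw frequency.
#' @param renormalize Recompute `frequency` over retained reads.
#' @return The filtered data.frame with a `frequency` column added/updated.
#' @export
filter_low_frequency <- function(variants, min_freq = 0.01,
                                 renormalize = TRUE) {
  total <- sum(variants$read_count)
  if (total <= 0) {
    stop(structure(class = c("calluscope_no_call", "error", "condition"),
                   list(message = "no reads at this line/locus (no-call)",
                        call = NULL)))
  }
  raw <- variants$read_count / total
  keep <- raw >= min_freq
  if (!any(keep)) {
    stop(structure(class = c("calluscope_no_call", "error", "condition"),
                   list(message = sprintf(
                     "all %d variants below the %.3g frequency threshold (no-call)",
                     nrow(variants), min_freq), call = NULL)))
  }
  out <- variants[keep, , drop = FALSE]
  out$frequency <- if (renormalize) {
    out$read_count / sum(out$read_count)
  } else {
    raw[keep]
  }
  rownames(out) <- NULL
  out
}

#' Classify read variants against a target by global alignment
#'
#' Each variant is globally aligned to the reference amplicon
#' (Needleman-Wunsch; match +2, mismatch -1, affine gaps). A variant with no
#' gaps and no mismatches is `wildtype`; mismatches only, `substitution`;
#' gaps only, `indel`; gaps and mismatches, `complex` (complex variants count
#' as indel-containing downstream). Substitutions are reported in protospacer
#' coordinates (position 1 = PAM-distal base); mismatches outside the
#' protospacer carry the amplicon coordinate and `in_protospacer = FALSE`.
#'
#' @param target A [target_spec()].
#' @param variant_seq Character vector of read-variant sequences.
#' @return List with one element per variant: `mutation_class`,
#'   `length_delta`, and `substitutions` (data.frame position/ref/alt/
#'   in_protospacer). For a single input the single element is returned
#'   directly by [classify_variant()].
#' @export
classify_variants <- function(target, variant_seq) {
  variant_seq <- check_dna(variant_seq, "variant_seq", allow_n = FALSE)
  if (any(nchar(variant_seq) == 0)) stopf("variant_seq must be non-empty")
  ref <- target$reference_amplicon
  empty_subs <- data.frame(position = integer(0), ref = character(0),
                           alt = character(0), in_protospacer = logical(0),
                           stringsAsFactors = FALSE)
  res <- vector("list", length(variant_seq))
  is_wt <- variant_seq == ref
  res[is_wt] <- list(list(mutation_class = "wildtype", length_delta = 0L,
                          substitutions = empty_subs))
  todo <- which(!is_wt)
  if (length(todo) == 0) return(res)

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(variant_seq[todo]),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  nind <- Biostrings::nindel(pa)
  n_gap_runs <- nind@insertion[, "Length"] + nind@deletion[, "Length"]
  mmt <- Biostrings::mismatchTable(pa)

  for (j in seq_along(todo)) {
    i <- todo[j]
    mm <- mmt[mmt$PatternId == j, , drop = FALSE]
    n_mm <- nrow(mm)
    gaps <- n_gap_runs[j]
    cls <- if (gaps == 0 && n_mm == 0) "wildtype"
    else if (gaps == 0) "substitution"
    else if (n_mm == 0) "indel"
    else "complex"
    subs <- empty_subs
    if (n_mm > 0) {
      apos <- mm$SubjectStart
      ps <- amplicon_to_protospacer(target, apos)
      inside <- !is.na(ps)
      ref_b <- as.character(mm$SubjectSubstring)
      alt_b <- as.character(mm$PatternSubstring)
      if (target$spacer_strand == "-") {
        # report protospacer-strand bases for in-window substitutions
        ref_b[inside] <- chartr("ACGT", "TGCA", ref_b[inside])
        alt_b[inside] <- chartr("ACGT", "TGCA", alt_b[inside])
      }
      subs <- data.frame(position = ifelse(inside, ps, apos),
                         ref = ref_b, alt = alt_b,
                         in_protospacer = inside,
                         stringsAsFactors = FALSE)
      subs <- subs[order(!subs$in_protospacer, subs$position), , drop = FALSE]
      rownames(subs) <- NULL
    }
    res[[i]] <- list(mutation_class = cls,
                     length_delta = nchar(variant_seq[i]) - nchar(ref),
                     substitutions = subs)
  }
  res
}

#' @rdname classify_variants
#' @export
classify_variant <- function(target, variant_seq) {
  stopifnot(length(variant_seq) == 1)
  classify_variants(target, variant_seq)[[1]]
}

format_substitutions <- function(subs) {
  if (nrow(subs) == 0) return("")
  paste(sprintf("%s%d:%s>%s", ifelse(subs$in_protospacer, "", "amp"),
                subs$position, subs$ref, subs$alt), collapse = ";")
}

#' Cumulative mutation and indel frequencies at one locus
#'
#' @param variants Filtered data.frame with `frequency` and `mutation_class`
#'   columns.
#' @return Named numeric vector `c(mutation_frequency, indel_frequency)`:
#'   the summed frequency of all non-wildtype variants, and of the variants
#'   whose class is `indel` or `complex`.
#' @export
locus_mutation_frequency <- function(variants) {
  edited <- variants$mutation_class != "wildtype"
  indel <- variants$mutation_class %in% c("indel", "complex")
  c(mutation_frequency = sum(variants$frequency[edited]),
    indel_frequency = sum(variants$frequency[indel]))
}

#' Classify zygosity from a cumulative mutation frequency
#'
#' Frequencies above 0.90 (strict) are homozygous, in \[0.20, 0.90\]
#' heterozygous, in (0, 0.20) chimeric, and exactly 0 wildtype.
#'
#' @param mutation_frequency Numeric vector in \[0, 1\].
#' @return Character vector of zygosity classes.
#' @export
classify_zygosity <- function(mutation_frequency) {
  if (any(mutation_frequency < 0 | mutation_frequency > 1 |
            !is.finite(mutation_frequency))) {
    stopf("mutation frequency must lie in [0, 1]")
  }
  ifelse(mutation_frequency > ZYGOSITY_HOMOZYGOUS, "homozygous",
         ifelse(mutation_frequency >= ZYGOSITY_HETEROZYGOUS, "heterozygous",
                ifelse(mutation_frequency > 0, "chimeric", "wildtype")))
}

#' Per-line call from its locus calls
#'
#' A line is edited when at least one locus is heterozygous or homozygous
#' (chimeric-only lines are not edited), homozygous when at least one locus
#' is homozygous. With the default `indel_rule = "frequency"` a line carries
#' indels when the cumulative indel frequency at some locus reaches the
#' heterozygous threshold (0.20) on its own; `"any"` flags any line with an
#' indel-class variant surviving the filter.
#'
#' @param locus_calls data.frame with columns `line_id`, `locus_id`,
#'   `zygosity`, `indel_frequency`, `has_indel_call` (one line only).
#' @param indel_rule `"frequency"` (default) or `"any"`.
#' @return One-row data.frame (line_id, n_loci, edited, homozygous,
#'   indel_line).
#' @export
call_line <- function(locus_calls, indel_rule = c("frequency", "any")) {
  indel_rule <- match.arg(indel_rule)
  if (nrow(locus_calls) < 1) stopf("need at least one locus call")
  if (length(unique(locus_calls$line_id)) != 1) {
    stopf("call_line expects locus calls of a single line")
  }
  edited <- any(locus_calls$zygosity %in% c("heterozygous", "homozygous"))
  homo <- any(locus_calls$zygosity == "homozygous")
  indel_line <- if (indel_rule == "frequency") {
    any(locus_calls$indel_frequency >= ZYGOSITY_HETEROZYGOUS)
  } else {
    any(locus_calls$has_indel_call)
  }
  data.frame(line_id = locus_calls$line_id[1], n_loci = nrow(locus_calls),
             edited = edited, homozygous = homo, indel_line = indel_line,
             stringsAsFactors = FALSE)
}

#' Cohort editing statistics from counts
#'
#' Rates are percentages of genotyped lines, rounded to one decimal with
#' halves away from zero.
#'
#' @param construct_id Construct label.
#' @param n_genotyped,n_edited,n_homozygous,n_indel Line counts.
#' @return One-row data.frame with the counts and editing_efficiency,
#'   homozygous_rate, indel_rate.
#' @export
cohort_summary <- function(construct_id, n_genotyped, n_edited,
                           n_homozygous, n_indel) {
  if (n_genotyped < 1) stopf("need at least one genotyped line")
  if (n_homozygous > n_edited || n_edited > n_genotyped) {
    stopf("expected n_homozygous <= n_edited <= n_genotyped")
  }
  rate <- function(k) round_half_up(100 * k / n_genotyped, 1)
  data.frame(construct_id = construct_id,
             n_genotyped = n_genotyped, n_edited = n_edited,
             n_homozygous = n_homozygous, n_indel = n_indel,
             editing_efficiency = rate(n_edited),
             homozygous_rate = rate(n_homozygous),
             indel_rate = rate(n_indel),
             stringsAsFactors = FALSE)
}

#' Cohort editing statistics from per-line calls
#'
#' @param line_calls data.frame of [call_line()] rows.
#' @param construct_id Construct label.
#' @return One-row data.frame, see [cohort_summary()].
#' @export
summarize_cohort <- function(line_calls, construct_id = "construct") {
  cohort_summary(construct_id,
                 n_genotyped = nrow(line_calls),
                 n_edited = sum(line_calls$edited),
                 n_homozygous = sum(line_calls$homozygous),
                 n_indel = sum(line_calls$indel_line))
}

#' Genotype a cohort of lines from an amplicon variant table
#'
#' Runs the full per-locus pipeline for every (line, locus): the 1% read
#' filter, alignment-based variant classification, cumulative mutation/indel
#' frequencies and the zygosity call; then per-line calls and per-construct
#' summaries. Loci whose variants are all filtered away are recorded as
#' no-calls (zygosity `NA`) with a warning and do not contribute to line
#' calls.
#'
#' @param variants data.frame (line_id, locus_id, variant_seq, read_count),
#'   optionally a `construct_id` column.
#' @param targets List of [target_spec()]; names or `locus_id` fields must
#'   cover every locus in `variants`.
#' @param min_freq Read-frequency exclusion threshold (default 0.01).
#' @param renormalize Recompute frequencies over retained reads.
#' @param indel_rule Passed to [call_line()].
#' @param construct_of Optional named vector line_id -> construct_id; used
#'   when `variants` has no `construct_id` column. A single unnamed value
#'   labels the whole cohort.
#' @return List of class `genotype_result`: `variants` (annotated),
#'   `locus_calls`, `line_calls`, `cohorts`.
#' @export
genotype_cohort <- function(variants, targets, min_freq = 0.01,
                            renormalize = TRUE,
                            indel_rule = c("frequency", "any"),
                            construct_of = NULL) {
  indel_rule <- match.arg(indel_rule)
  if (is.null(names(targets))) {
    names(targets) <- vapply(targets, `[[`, character(1), "locus_id")
  }
  missing_loci <- setdiff(unique(variants$locus_id), names(targets))
  if (length(missing_loci) > 0) {
    stopf("no target spec for locus/loci: %s",
          paste(missing_loci, collapse = ", "))
  }

  if (!"construct_id" %in% names(variants)) {
    variants$construct_id <- if (is.null(construct_of)) "construct"
    else if (is.null(names(construct_of)) && length(construct_of) == 1) {
      construct_of
    } else {
      unname(construct_of[variants$line_id])
    }
  }

  groups <- split(variants,
                  list(variants$line_id, variants$locus_id), drop = TRUE)
  ann_list <- list()
  locus_rows <- list()
  for (g in groups) {
    line <- g$line_id[1]; locus <- g$locus_id[1]
    filt <- tryCatch(filter_low_frequency(g, min_freq, renormalize),
                     calluscope_no_call = function(e) NULL)
    if (is.null(filt)) {
      warning(sprintf("line %s, locus %s: %s", line, locus, "no variant above the read filter (no-call)"),
              call. = FALSE)
      locus_rows[[length(locus_rows) + 1L]] <- data.frame(
        line_id = line, locus_id = locus, construct_id = g$construct_id[1],
        n_variants = 0L, mutation_frequency = NA_real_,
        indel_frequency = NA_real_, zygosity = NA_character_,
        has_indel_call = NA, stringsAsFactors = FALSE)
      next
    }
    cls <- classify_variants(targets[[locus]], filt$variant_seq)
    filt$mutation_class <- vapply(cls, `[[`, character(1), "mutation_class")
    filt$length_delta <- vapply(cls, `[[`, integer(1), "length_delta")
    filt$substitutions <- vapply(cls, function(x) format_substitutions(x$substitutions),
                                 character(1))
    ann_list[[length(ann_list) + 1L]] <- filt
    freqs <- locus_mutation_frequency(filt)
    locus_rows[[length(locus_rows) + 1L]] <- data.frame(
      line_id = line, locus_id = locus, construct_id = g$construct_id[1],
      n_variants = nrow(filt),
      mutation_frequency = unname(freqs["mutation_frequency"]),
      indel_frequency = unname(freqs["indel_frequency"]),
      zygosity = unname(classify_zygosity(freqs[["mutation_frequency"]])),
      has_indel_call = any(filt$mutation_class %in% c("indel", "complex")),
      stringsAsFactors = FALSE)
  }
  annotated <- do.call(rbind, ann_list)
  locus_calls <- do.call(rbind, locus_rows)
  locus_calls <- locus_calls[order(locus_calls$line_id, locus_calls$locus_id), ,
                             drop = FALSE]
  rownames(locus_calls) <- NULL

  called <- locus_calls[!is.na(locus_calls$zygosity), , drop = FALSE]
  line_calls <- do.call(rbind, lapply(split(called, called$line_id),
                                      call_line, indel_rule = indel_rule))
  line_calls$construct_id <- locus_calls$construct_id[
    match(line_calls$line_id, locus_calls$line_id)]
  rownames(line_calls) <- NULL

  cohorts <- do.call(rbind, lapply(split(line_calls, line_calls$construct_id),
                                   function(lc) summarize_cohort(lc, lc$construct_id[1])))
  rownames(cohorts) <- NULL

  structure(list(variants = annotated, locus_calls = locus_calls,
                 line_calls = line_calls, cohorts = cohorts),
            class = "genotype_result")
}

#' Write genotyping results to a directory
#'
#' @param result A `genotype_result` from [genotype_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_genotype_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$variants, file.path(dir, "variants_annotated.tsv"))
  write_tsv(result$locus_calls, file.path(dir, "locus_calls.tsv"))
  write_tsv(result$line_calls, file.path(dir, "line_calls.tsv"))
  write_tsv(result$cohorts, file.path(dir, "cohort_summary.tsv"))
  invisible(dir)
}
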