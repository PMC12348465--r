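# Seeded synthetic-data generators. Every generator is a pure function of its
# arguments (including the seed) and returns a ground-truth manifest
# sufficient to verify recovery without re-simulation.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

DEFAULT_TISSUES <- c("root", "stem", "leaf", "flower", "peg",
                     "seed_R3", "seed_R6", "seed_R8", "shoot", "pod",
                     "nodule", "pericarp", "seedling", "cotyledon",
                     "embryo", "testa", "gynophore", "mainstem_leaf",
                     "lateral_leaf", "perianth", "stamen", "pistil")

#' Simulate a multi-tissue expression atlas with planted specific genes
#'
#' Emulates the screen's input: two callus subculture stages (t5, t11) with
#' `n_replicates` samples each, plus one sample per non-callus tissue.
#' Baseline per-gene expression is log-normal (meanlog 1, sdlog 1.5) shared
#' across samples, with multiplicative log-normal replicate noise (sdlog
#' 0.2). Planted callus-specific genes have their callus expression
#' multiplied by `effect_fold` (baselines resampled so the planted callus
#' signal is at least 50 FPKM, i.e. several-fold above the default screen
#' thresholds) and their other-tissue expression drawn from the
#' sub-threshold regime U(0, 0.5).
#'
#' @param n_genes Total genes (default 2000).
#' @param n_tissues Number of non-callus tissues (default 10).
#' @param n_replicates Callus replicates per stage (default 3).
#' @param n_specific Number of planted callus-specific genes (default 20).
#' @param effect_fold Callus fold-boost of planted genes (default 100).
#' @param seed Integer seed.
#' @return List: `values` (gene x sample FPKM matrix), `samples` (sample
#'   sheet data.frame), `atlas` (an [expression_atlas()]), `manifest` (list
#'   with `seed` and `specific_genes`).
#' @export
simulate_expression_atlas <- function(n_genes = 2000, n_tissues = 10,
                                      n_replicates = 3, n_specific = 20,
                                      effect_fold = 100, seed = 1) {
  if (n_specific > n_genes) stopf("n_specific must not exceed n_genes")
  if (n_genes < 1 || n_tissues < 1 || n_replicates < 1) {
    stopf("sizes must be positive")
  }
  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    tissues <- if (n_tissues <= length(DEFAULT_TISSUES)) {
      DEFAULT_TISSUES[seq_len(n_tissues)]
    } else {
      c(DEFAULT_TISSUES,
        sprintf("tissue_%02d", seq_len(n_tissues - length(DEFAULT_TISSUES))))
    }
    callus_samples <- as.vector(outer(c("t5", "t11"), seq_len(n_replicates),
                                      function(s, r) sprintf("callus_%s_rep%d", s, r)))
    samples <- data.frame(
      sample_id = c(callus_samples, tissues),
      tissue = c(rep("callus", length(callus_samples)), tissues),
      stage = c(rep(c("t5", "t11"), n_replicates), rep(NA_character_,
                                                       length(tissues))),
      stringsAsFactors = FALSE
    )
    baseline <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1.5)
    specific <- sort(sample(n_genes, n_specific))
    min_callus_signal <- 50
    if (n_specific > 0) {
      low <- baseline[specific] * effect_fold < min_callus_signal
      while (any(low)) {
        baseline[specific[low]] <- stats::rlnorm(sum(low), 1, 1.5)
        low <- baseline[specific] * effect_fold < min_callus_signal
      }
    }
    values <- matrix(0, n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      noise <- stats::rlnorm(n_genes, 0, 0.2)
      values[, j] <- baseline * noise
    }
    if (n_specific > 0) {
      is_callus <- samples$tissue == "callus"
      values[specific, is_callus] <- values[specific, is_callus] * effect_fold
      values[specific, !is_callus] <-
        matrix(stats::runif(n_specific * sum(!is_callus), 0, 0.5),
               n_specific, sum(!is_callus))
    }
    tissue_of <- stats::setNames(samples$tissue, samples$sample_id)
    list(values = values, samples = samples,
         atlas = expression_atlas(values, tissue_of),
         manifest = list(seed = seed, specific_genes = genes[specific],
                         effect_fold = effect_fold,
                         n_genes = n_genes, n_tissues = n_tissues))
  })
}

#' Simulate a two-stage screen input with designed top-N set sizes
#'
#' Constructs per-replicate FPKM values such that each replicate's exact
#' top-`top_n` set is a designed window of that stage's gene set, the
#' within-stage unions have exactly the designed `stage_sizes`, and the two
#' stage sets overlap in exactly `overlap` genes. Values inside a replicate's
#' window are distinct and strictly above all other genes' values, so the
#' top-N selection has no ties at the cutoff.
#'
#' @param n_genes Gene universe size (default 2000).
#' @param top_n Per-replicate selection size (default 400).
#' @param stage_sizes Named integer vector of designed within-stage union
#'   sizes (default `c(t5 = 487, t11 = 453)`).
#' @param overlap Designed size of the cross-stage intersection (default
#'   419).
#' @param n_replicates Replicates per stage (default 3).
#' @param seed Integer seed (background values only; the set structure is
#'   deterministic).
#' @return List: `values`, `samples`, `manifest` (stage gene sets,
#'   per-replicate designed top sets, overlap genes).
#' @export
simulate_staged_atlas <- function(n_genes = 2000, top_n = 400,
                                  stage_sizes = c(t5 = 487, t11 = 453),
                                  overlap = 419, n_replicates = 3,
                                  seed = 1) {
  if (any(stage_sizes < top_n) || any(stage_sizes > n_replicates * top_n)) {
    stopf("each stage size must lie in [top_n, n_replicates * top_n]")
  }
  if (overlap > min(stage_sizes)) stopf("overlap exceeds a stage size")
  total_union <- sum(stage_sizes) - overlap
  if (total_union > n_genes) stopf("n_genes too small for the designed sets")
  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    # stage 1 occupies genes 1..s1; stage 2 starts so the tail overlap is
    # exactly `overlap`
    s1 <- stage_sizes[[1]]; s2 <- stage_sizes[[2]]
    stage_idx <- list(seq_len(s1),
                      seq(s1 - overlap + 1L, s1 - overlap + s2))
    names(stage_idx) <- names(stage_sizes) %||% c("stage1", "stage2")
    samples <- data.frame(
      sample_id = as.vector(vapply(names(stage_idx), function(st) {
        sprintf("callus_%s_rep%d", st, seq_len(n_replicates))
      }, character(n_replicates))),
      tissue = "callus",
      stage = rep(names(stage_idx), each = n_replicates),
      stringsAsFactors = FALSE
    )
    values <- matrix(stats::runif(n_genes * nrow(samples), 0, 50),
                     n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    rep_windows <- list()
    for (st in names(stage_idx)) {
      idx <- stage_idx[[st]]
      size <- length(idx)
      offsets <- round(seq(0, size - top_n, length.out = n_replicates))
      for (r in seq_len(n_replicates)) {
        window <- idx[seq(offsets[r] + 1L, offsets[r] + top_n)]
        col <- sprintf("callus_%s_rep%d", st, r)
        values[window, col] <- seq(1000, 101, length.out = top_n)
        rep_windows[[col]] <- genes[window]
      }
    }
    list(values = values, samples = samples,
         manifest = list(seed = seed,
                         stage_sets = lapply(stage_idx, function(i) genes[i]),
                         replicate_tops = rep_windows,
                         overlap_genes = genes[intersect(stage_idx[[1]],
                                                         stage_idx[[2]])]))
  })
}

#' Default editing target pair for simulations
#'
#' Two synthetic amplicons carrying a shared 20-nt spacer with an NGG PAM,
#' standing in for the homoeologous A- and B-subgenome loci of an
#' acetolactate-synthase gene targeted at its P197 codon region. The
#' sequences are synthetic; only their structure (spacer at a known position,
#' PAM 3' of it) matters to the pipeline.
#'
#' @param seed Integer seed for the flanking sequence.
#' @return Named list of two [target_spec()] objects.
#' @export
default_targets <- function(seed = 101) {
  with_seed(seed, {
    spacer <- random_dna(20)
    mk <- function(locus) {
      left <- random_dna(40)
      right <- random_dna(40)
      pam <- paste0(sample(c("A", "C", "G", "T"), 1), "GG")
      amp <- paste0(left, spacer, pam, right)
      target_spec(locus_id = locus, reference_amplicon = amp,
                  spacer = spacer, pam = "NGG",
                  protospacer_start = nchar(left) + 1L, spacer_strand = "+")
    }
    list(`ALS2-A` = mk("ALS2-A"), `ALS2-B` = mk("ALS2-B"))
  })
}

# One edited variant sequence for a target: C->T substitution at protospacer
# position `sub_pos` (falling back to the first C in the window, else any
# position, substituted to a different base), or a 1-bp deletion inside the
# protospacer when `indel`.
edited_variant <- function(target, indel = FALSE, sub_pos = 5L) {
  ref <- target$reference_amplicon
  start <- target$protospacer_start
  if (indel) {
    del_at <- start + 9L
    return(paste0(substring(ref, 1, del_at - 1L),
                  substring(ref, del_at + 1L, nchar(ref))))
  }
  window <- strsplit(substring(ref, start, start + 19L), "")[[1]]
  pos <- if (window[sub_pos] == "C") sub_pos else {
    cand <- which(window == "C")
    if (length(cand) > 0) cand[1] else sub_pos
  }
  base <- window[pos]
  alt <- if (base == "C") "T" else setdiff(c("A", "C", "G", "T"), base)[1]
  apos <- start + pos - 1L
  paste0(substring(ref, 1, apos - 1L), alt,
         substring(ref, apos + 1L, nchar(ref)))
}

# A noise variant: one random substitution outside the protospacer.
noise_variant <- function(target, avoid = character(0)) {
  ref <- target$reference_amplicon
  start <- target$protospacer_start
  repeat {
    pos <- sample(nchar(ref), 1)
    if (pos >= start - 3L && pos <= start + 22L) next
    base <- substring(ref, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    v <- paste0(substring(ref, 1, pos - 1L), alt,
                substring(ref, pos + 1L, nchar(ref)))
    if (!v %in% avoid) return(v)
  }
}

design_frequency <- function(zygosity) {
  switch(zygosity,
         homozygous = stats::runif(1, 0.91, 1.0),
         heterozygous = stats::runif(1, 0.20, 0.90),
         chimeric = stats::runif(1, 0.01, 0.19),
         wildtype = 0,
         stopf("unknown zygosity class '%s'", zygosity))
}

#' Simulate an amplicon-sequencing cohort with designed outcomes
#'
#' For every line and locus, the designed zygosity class draws an edited-read
#' fraction from its frequency band (homozygous U(0.91, 1), heterozygous
#' U(0.20, 0.90), chimeric U(0.01, 0.19), wildtype 0); read counts are then
#' multinomial over (wildtype, edited, noise) frequencies at the given depth.
#' Draws are rejection-sampled (bounded retries) until the realised
#' post-filter read population reproduces the designed class, so the manifest
#' is exact ground truth for recovery tests. Edited variants are C-to-T
#' substitutions in the protospacer, or 1-bp deletions for lines flagged
#' `indel`. Noise variants are single substitutions outside the protospacer,
#' each held below the 1% read filter.
#'
#' @param targets Named list of [target_spec()] (default [default_targets()]).
#' @param line_designs data.frame with `line_id`, one zygosity column per
#'   locus (named as in `targets`), and logical `indel`. See
#'   [design_cohort()].
#' @param depth Reads per line/locus (>= 100; default 5000).
#' @param noise_rate Total read fraction allocated to sub-threshold noise
#'   variants (default 0).
#' @param seed Integer seed.
#' @param construct_id Construct label attached to the table.
#' @return List: `variants` (data.frame line_id, locus_id, variant_seq,
#'   read_count, construct_id), `manifest` (designs, design frequencies,
#'   expected cohort counts).
#' @export
simulate_amplicon_cohort <- function(targets = default_targets(),
                                     line_designs, depth = 5000,
                                     noise_rate = 0, seed = 1,
                                     construct_id = "construct") {
  if (depth < 100) stopf("depth must be >= 100")
  loci <- names(targets)
  miss <- setdiff(loci, names(line_designs))
  if (length(miss) > 0) stopf("line_designs missing locus column(s): %s",
                              paste(miss, collapse = ", "))
  ok_classes <- c("wildtype", "chimeric", "heterozygous", "homozygous")
  for (lc in loci) {
    bad <- setdiff(unique(line_designs[[lc]]), ok_classes)
    if (length(bad) > 0) stopf("unknown zygosity class(es): %s",
                               paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(line_designs))) {
      line <- line_designs$line_id[i]
      indel <- isTRUE(line_designs$indel[i])
      for (lc in loci) {
        target <- targets[[lc]]
        zyg <- line_designs[[lc]][i]
        counts <- NULL
        f <- NA_real_
        for (try in 1:200) {
          f <- design_frequency(zyg)
          seqs <- target$reference_amplicon
          freqs <- 1 - f
          if (f > 0) {
            seqs <- c(seqs, edited_variant(target, indel = indel))
            freqs <- c(freqs, f)
          }
          if (noise_rate > 0) {
            n_noise <- max(1L, ceiling(noise_rate / 0.009))
            nv <- character(0)
            for (k in seq_len(n_noise)) nv <- c(nv, noise_variant(target, avoid = c(seqs, nv)))
            per_noise <- noise_rate / n_noise
            freqs <- c(freqs * (1 - noise_rate), rep(per_noise, n_noise))
            seqs <- c(seqs, nv)
          }
          cnt <- as.vector(stats::rmultinom(1, depth, freqs))
          # verify the realised population encodes the design
          main <- cnt[seq_len(if (f > 0) 2 else 1)]
          kept <- cnt / depth >= 0.01
          if (noise_rate > 0 && any(kept[-seq_along(main)])) next
          edited_reads <- if (f > 0 && kept[2]) cnt[2] else 0
          kept_main <- sum(cnt[seq_along(main)][kept[seq_along(main)]])
          if (kept_main == 0) next
          emp <- edited_reads / kept_main
          if (classify_zygosity(emp) != zyg) next
          counts <- cnt
          break
        }
        if (is.null(counts)) {
          stopf("could not realise design %s at %s/%s within retry budget",
                zyg, line, lc)
        }
        keep <- counts > 0
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = line, locus_id = lc, variant_seq = seqs[keep],
          read_count = counts[keep], construct_id = construct_id,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          line_id = line, locus_id = lc, zygosity = zyg,
          indel = indel && zyg != "wildtype", design_frequency = f,
          stringsAsFactors = FALSE)
      }
    }
    variants <- do.call(rbind, rows)
    truth <- do.call(rbind, truth)
    edited_lines <- vapply(split(truth, truth$line_id), function(tr) {
      any(tr$zygosity %in% c("heterozygous", "homozygous"))
    }, logical(1))
    homo_lines <- vapply(split(truth, truth$line_id), function(tr) {
      any(tr$zygosity == "homozygous")
    }, logical(1))
    indel_lines <- vapply(split(truth, truth$line_id), function(tr) {
      any(tr$indel & tr$zygosity %in% c("heterozygous", "homozygous"))
    }, logical(1))
    list(variants = variants,
         manifest = list(seed = seed, construct_id = construct_id,
                         depth = depth, noise_rate = noise_rate,
                         truth = truth,
                         expected_counts = c(
                           n_genotyped = nrow(line_designs),
                           n_edited = sum(edited_lines),
                           n_homozygous = sum(homo_lines),
                           n_indel = sum(indel_lines))))
  })
}

#' Build a per-line design table from cohort counts
#'
#' Produces `n_genotyped` line designs of which `n_edited` are edited
#' (`n_homozygous` of those homozygous, the rest heterozygous) at the first
#' locus and wildtype at the second, and `n_indel` of the edited lines carry
#' their edit as a 1-bp deletion rather than a base substitution. Remaining
#' lines are wildtype at both loci.
#'
#' @param n_genotyped,n_edited,n_homozygous,n_indel Designed line counts
#'   (`n_homozygous <= n_edited <= n_genotyped`, `n_indel <= n_edited`).
#' @param loci Locus names (default the two loci of [default_targets()]).
#' @param line_prefix Prefix for generated line ids.
#' @return data.frame suitable for [simulate_amplicon_cohort()].
#' @export
design_cohort <- function(n_genotyped, n_edited, n_homozygous, n_indel,
                          loci = c("ALS2-A", "ALS2-B"),
                          line_prefix = "line") {
  if (n_homozygous > n_edited || n_edited > n_genotyped) {
    stopf("need n_homozygous <= n_edited <= n_genotyped")
  }
  if (n_indel > n_edited) stopf("n_indel must not exceed n_edited")
  zyg1 <- c(rep("homozygous", n_homozygous),
            rep("heterozygous", n_edited - n_homozygous),
            rep("wildtype", n_genotyped - n_edited))
  df <- data.frame(line_id = sprintf("%s_%02d", line_prefix,
                                     seq_len(n_genotyped)),
                   stringsAsFactors = FALSE)
  df[[loci[1]]] <- zyg1
  for (lc in loci[-1]) df[[lc]] <- "wildtype"
  df$indel <- c(rep(TRUE, n_indel), rep(FALSE, n_genotyped - n_indel))
  df
}

#' Published cohort designs for the six evaluated constructs
#'
#' The genotyped / edited / homozygous / indel line counts of the six
#' promoter-CBE constructs (35S and the five callus-specific promoters), as
#' inputs for [design_cohort()] + [simulate_amplicon_cohort()].
#'
#' @return data.frame (construct_id, n_genotyped, n_edited, n_homozygous,
#'   n_indel).
#' @export
published_cohort_counts <- function() {
  data.frame(
    construct_id = c("35S-CBE", "PAh-H0FE8D-CBE", "PAh-WT3AEF-CBE",
                     "PAh-I20Q6X-CBE", "PAh-ELJ55T-CBE", "PAh-N9CMH4-CBE"),
    n_genotyped = c(28L, 28L, 28L, 28L, 24L, 28L),
    n_edited = c(4L, 6L, 4L, 2L, 5L, 8L),
    n_homozygous = c(2L, 2L, 4L, 0L, 3L, 3L),
    n_indel = c(2L, 3L, 2L, 2L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Simulate promoters with planted motifs
#'
#' Background sequence is uniform over A/C/G/T; each planted motif is written
#' at its stated coordinate as a concrete realisation of its IUPAC pattern
#' (reverse-complemented for `-`-strand plants). Overlapping planted motifs
#' within one promoter are an error.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp (default 2000).
#' @param planted data.frame with columns `motif_name`, `pattern`,
#'   `position` (1-based start), `strand`; optional `promoter_id` restricts a
#'   plant to one promoter (default: planted in every promoter).
#' @param seed Integer seed.
#' @return List: `sequences` (named character), `manifest` (data.frame
#'   promoter_id, motif_name, start, end, strand, planted_seq).
#' @export
simulate_promoters <- function(n, length = 2000, planted = NULL, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("promoter_%02d", seq_len(n))
    seqs <- stats::setNames(vapply(ids, function(i) random_dna(length),
                                   character(1)), ids)
    manifest <- NULL
    if (!is.null(planted) && nrow(planted) > 0) {
      rows <- list()
      for (id in ids) {
        pl <- planted
        if ("promoter_id" %in% names(pl)) {
          pl <- pl[pl$promoter_id == id, , drop = FALSE]
        }
        if (nrow(pl) == 0) next
        ends <- pl$position + nchar(pl$pattern) - 1L
        if (any(ends > length) || any(pl$position < 1)) {
          stopf("planted motif does not fit within the promoter")
        }
        o <- order(pl$position)
        if (any(pl$position[o][-1] <= ends[o][-nrow(pl)])) {
          stopf("planted motifs overlap in promoter %s", id)
        }
        s <- seqs[[id]]
        for (j in seq_len(nrow(pl))) {
          realization <- paste(vapply(
            strsplit(check_iupac(pl$pattern[j]), "")[[1]],
            function(ch) sample(IUPAC_CODES[[ch]], 1), character(1)),
            collapse = "")
          written <- if (pl$strand[j] == "-") revcomp(realization) else realization
          s <- paste0(substring(s, 1, pl$position[j] - 1L), written,
                      substring(s, pl$position[j] + nchar(written), length))
          rows[[length(rows) + 1L]] <- data.frame(
            promoter_id = id, motif_name = pl$motif_name[j],
            start = pl$position[j], end = ends[j], strand = pl$strand[j],
            planted_seq = written, stringsAsFactors = FALSE)
        }
        seqs[[id]] <- s
      }
      manifest <- do.call(rbind, rows)
    }
    list(sequences = seqs,
         manifest = list(seed = seed, planted = manifest))
  })
}

#' Simulate a genome with planted off-target sites
#'
#' Plants, over a uniform-random background, one site per entry of
#' `planted_mismatch_counts`: a 20-mer at exactly that Hamming distance from
#' the spacer followed by a concrete NGG PAM, alternating between the two
#' strands. The genome is verified with a full scan and re-sampled (bounded
#' retries) if any accidental site within `verify_max_mismatches` appears, so
#' the manifest lists exactly the qualifying sites.
#'
#' @param spacer 20-nt spacer.
#' @param planted_mismatch_counts Integer vector; one planted site per entry
#'   (0 = the on-target itself).
#' @param length Genome length in bp (default 100000).
#' @param seed Integer seed.
#' @param verify_max_mismatches Collision-check budget (default
#'   `max(planted_mismatch_counts, 4)`).
#' @param max_retries Genome re-draws before giving up (default 20).
#' @return List: `sequences` (named character of length 1), `manifest`
#'   (data.frame seq_id, start, end, strand, n_mismatches, site_seq,
#'   pam_seq).
#' @export
simulate_genome_with_offtargets <- function(spacer, planted_mismatch_counts,
                                            length = 100000, seed = 1,
                                            verify_max_mismatches = NULL,
                                            max_retries = 20) {
  spacer <- check_dna(spacer, "spacer", allow_n = FALSE)
  if (nchar(spacer) != 20) stopf("spacer must be 20 nt")
  verify_mm <- verify_max_mismatches %||%
    max(c(planted_mismatch_counts, 4L))
  site_len <- 23L
  n_sites <- length(planted_mismatch_counts)
  if (n_sites * (site_len + 20L) > length) stopf("genome too short for the planted sites")
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      g <- random_dna(length)
      # evenly spaced slots with jitter keep planted sites non-overlapping
      slot <- floor(length / n_sites)
      starts <- vapply(seq_len(n_sites), function(i) {
        lo <- (i - 1L) * slot + 1L
        hi <- i * slot - site_len
        as.integer(sample(seq(lo, hi), 1))
      }, integer(1))
      spacer_chars <- strsplit(spacer, "")[[1]]
      rows <- list()
      for (i in seq_len(n_sites)) {
        k <- planted_mismatch_counts[i]
        site <- spacer_chars
        if (k > 0) {
          mmpos <- sample(20L, k)
          for (p in mmpos) site[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                     site[p]), 1)
        }
        pam <- paste0(sample(c("A", "C", "G", "T"), 1), "GG")
        site_seq <- paste(site, collapse = "")
        strand <- if (i %% 2 == 1) "+" else "-"
        cassette <- paste0(site_seq, pam)
        written <- if (strand == "-") revcomp(cassette) else cassette
        g <- paste0(substring(g, 1, starts[i] - 1L), written,
                    substring(g, starts[i] + site_len, length))
        proto_start <- if (strand == "+") starts[i] else starts[i] + 3L
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = "chr_sim", start = proto_start,
          end = proto_start + 19L, strand = strand,
          n_mismatches = as.integer(k), site_seq = site_seq, pam_seq = pam,
          stringsAsFactors = FALSE)
      }
      manifest <- do.call(rbind, rows)
      sequences <- c(chr_sim = g)
      found <- enumerate_sites(sequences,
                               guide_spec(spacer, max_mismatches = verify_mm))
      key <- function(df) paste(df$seq_id, df$strand, df$start)
      if (nrow(found) == nrow(manifest) &&
            setequal(key(found), key(manifest))) {
        return(list(sequences = sequences,
                    manifest = list(seed = seed, spacer = spacer,
                                    sites = manifest)))
      }
    }
    stopf("could not place planted sites without accidental matches after %d retries",
          max_retries)
  })
}
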