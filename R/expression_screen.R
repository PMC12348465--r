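# Tissue-specific (callus-specific) candidate gene screen:
# per-replicate top-N selection -> within-stage consensus (union) ->
# cross-stage intersection -> expression-atlas specificity filter.

#' Construct an expression atlas
#'
#' Bundles a non-negative gene x sample expression matrix with a
#' sample-to-tissue assignment (and optional gene lengths, needed only when
#' the values are raw fragment counts).
#'
#' @param values Non-negative numeric matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param tissue_of Named character vector mapping every sample id to a
#'   tissue label.
#' @param gene_lengths Optional named numeric vector of gene lengths (bp),
#'   required when `values` holds raw counts.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(values, tissue_of, gene_lengths = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("gene ids must be unique")
  if (any(values < 0)) stopf("expression values must be non-negative")
  miss <- setdiff(colnames(values), names(tissue_of))
  if (length(miss) > 0) {
    stopf("samples without a tissue label: %s", paste(miss, collapse = ", "))
  }
  if (!is.null(gene_lengths)) {
    lmiss <- setdiff(rownames(values), names(gene_lengths))
    if (length(lmiss) > 0) {
      stopf("gene_lengths missing for: %s", paste(utils::head(lmiss, 5), collapse = ", "))
    }
  }
  structure(list(values = values,
                 tissue_of = tissue_of[colnames(values)],
                 gene_lengths = gene_lengths),
            class = "expression_atlas")
}

#' Screen configuration
#'
#' Thresholds for the top-N selection and the atlas specificity filter.
#' The specificity thresholds are expressed in FPKM; the ratio uses a
#' pseudocount so genes silent in all other tissues do not divide by zero.
#'
#' @param top_n Number of top-expressed genes selected per replicate
#'   (ties at the cutoff are all included).
#' @param callus_tissue Tissue label of the target tissue.
#' @param min_callus_expr Minimum expression in the target tissue (FPKM).
#' @param max_other_expr Maximum tolerated expression in any other tissue.
#' @param min_ratio Minimum target/max-other fold change (>= 1).
#' @param pseudocount Added to both sides of the ratio.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(top_n = 400, callus_tissue = "callus",
                          min_callus_expr = 10, max_other_expr = 1,
                          min_ratio = 10, pseudocount = 0.01) {
  if (top_n < 1) stopf("top_n must be >= 1")
  if (min_ratio < 1) stopf("min_ratio must be >= 1")
  if (min_callus_expr <= max_other_expr) {
    stopf("min_callus_expr must exceed max_other_expr")
  }
  structure(list(top_n = top_n, callus_tissue = callus_tissue,
                 min_callus_expr = min_callus_expr,
                 max_other_expr = max_other_expr,
                 min_ratio = min_ratio, pseudocount = pseudocount),
            class = "screen_config")
}

#' Convert fragment counts to FPKM
#'
#' FPKM = fragments * 1e9 / (library_size * gene_length_bp). A zero count
#' always maps to zero FPKM.
#'
#' @param counts Non-negative gene x sample count matrix (gene rownames).
#' @param gene_lengths Named numeric vector of gene lengths in bp; must cover
#'   every gene with a nonzero count.
#' @param library_sizes Total mapped fragments per sample; defaults to the
#'   column sums of `counts`.
#' @return FPKM matrix of the same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths,
                         library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  lens <- gene_lengths[rownames(counts)]
  bad <- is.na(lens) & rowSums(counts) > 0
  if (any(bad)) {
    stopf("missing gene length for gene(s) with nonzero counts: %s",
          paste(utils::head(rownames(counts)[bad], 5), collapse = ", "))
  }
  lens[is.na(lens)] <- 1  # zero-count rows only; result stays zero
  if (any(lens <= 0)) stopf("gene lengths must be positive")
  fpkm <- counts * 1e9 / outer(lens, library_sizes)
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Top-N expressed genes of one sample
#'
#' Returns the genes with the `n` highest values. All genes tied with the
#' n-th value are included, so the result can exceed `n`; with fewer than `n`
#' genes all are returned.
#'
#' @param expr Named numeric vector (gene -> expression).
#' @param n Positive integer.
#' @return Character vector of gene ids (unordered set).
#' @export
top_n_genes <- function(expr, n) {
  if (n < 1) stopf("n must be >= 1")
  if (length(expr) == 0) return(character(0))
  if (is.null(names(expr))) stopf("expr must be a named vector")
  if (length(expr) <= n) return(names(expr))
  cutoff <- sort(expr, decreasing = TRUE)[n]
  names(expr)[expr >= cutoff]
}

#' Within-stage consensus of per-replicate top-N sets
#'
#' The consensus is the union: a gene highly expressed in any replicate of a
#' stage counts as highly expressed at that stage.
#'
#' @param per_replicate_sets Non-empty list of character vectors.
#' @return Character vector (the union).
#' @export
stage_consensus <- function(per_replicate_sets) {
  if (length(per_replicate_sets) < 1) stopf("need at least one replicate set")
  unique(unlist(per_replicate_sets, use.names = FALSE))
}

#' Intersection of stage consensus sets
#'
#' @param stage_sets List of >= 2 character vectors.
#' @return Character vector of genes present in every stage set.
#' @export
cross_stage_intersection <- function(stage_sets) {
  if (length(stage_sets) < 2) stopf("need at least two stage sets")
  Reduce(intersect, stage_sets)
}

# Mean expression per tissue (columns of the atlas grouped by tissue label).
tissue_means <- function(atlas) {
  tissues <- unique(atlas$tissue_of)
  m <- vapply(tissues, function(tt) {
    cols <- names(atlas$tissue_of)[atlas$tissue_of == tt]
    rowMeans(atlas$values[, cols, drop = FALSE])
  }, numeric(nrow(atlas$values)))
  colnames(m) <- tissues
  m
}

#' Tissue-specificity filter against an expression atlas
#'
#' Keeps candidate genes whose target-tissue expression is at least
#' `min_callus_expr`, whose maximum expression over every other tissue is at
#' most `max_other_expr`, and whose (pseudocounted) target/max-other ratio is
#' at least `min_ratio`. Per-tissue expression is the mean over that tissue's
#' samples.
#'
#' @param candidates Character vector of gene ids to test.
#' @param atlas An [expression_atlas()].
#' @param cfg A [screen_config()].
#' @return data.frame (gene_id, callus_expr, max_other_expr,
#'   max_other_tissue, ratio) ordered by decreasing target-tissue expression.
#' @export
tissue_specificity_filter <- function(candidates, atlas, cfg = screen_config()) {
  if (!cfg$callus_tissue %in% atlas$tissue_of) {
    stopf("tissue '%s' not present in the atlas", cfg$callus_tissue)
  }
  tm <- tissue_means(atlas)
  candidates <- intersect(candidates, rownames(tm))
  callus <- tm[candidates, cfg$callus_tissue]
  others <- tm[candidates, setdiff(colnames(tm), cfg$callus_tissue), drop = FALSE]
  if (ncol(others) == 0) stopf("atlas has no non-target tissues to compare against")
  max_other <- apply(others, 1, max)
  which_other <- colnames(others)[apply(others, 1, which.max)]
  ratio <- (callus + cfg$pseudocount) / (max_other + cfg$pseudocount)
  keep <- callus >= cfg$min_callus_expr &
    max_other <= cfg$max_other_expr &
    ratio >= cfg$min_ratio
  out <- data.frame(gene_id = candidates,
                    callus_expr = callus,
                    max_other_expr = max_other,
                    max_other_tissue = which_other,
                    ratio = ratio,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$callus_expr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full tissue-specific gene screen
#'
#' Per-replicate top-N selection on the target-tissue samples, union within
#' stage, intersection across stages, then (when the atlas carries other
#' tissues) the specificity filter on the surviving genes. When `values`
#' holds raw counts, supply `gene_lengths` and set `units = "counts"` — FPKM
#' is computed with per-sample library sizes equal to the column sums.
#'
#' @param values Gene x sample matrix (FPKM, or counts with
#'   `units = "counts"`).
#' @param samples Sample sheet data.frame with columns `sample_id`, `tissue`,
#'   `stage` (stage required for target-tissue samples).
#' @param cfg A [screen_config()].
#' @param units `"fpkm"` (default) or `"counts"`.
#' @param gene_lengths Named numeric vector, required for `units = "counts"`.
#' @param de_table Optional data.frame (gene, log2FC, FDR) merged onto the
#'   candidate table as annotation only.
#' @return List of class `screen_result`: `per_replicate_top` (named list of
#'   gene sets), `stage_consensus` (named list), `cross_stage` (character),
#'   `specific_candidates` (data.frame), `summary` (named sizes).
#' @export
run_expression_screen <- function(values, samples, cfg = screen_config(),
                                  units = c("fpkm", "counts"),
                                  gene_lengths = NULL, de_table = NULL) {
  units <- match.arg(units)
  if (units == "counts") {
    if (is.null(gene_lengths)) stopf("counts input requires gene_lengths")
    values <- compute_fpkm(values, gene_lengths)
  }
  samples <- samples[samples$sample_id %in% colnames(values), , drop = FALSE]
  tissue_of <- stats::setNames(samples$tissue, samples$sample_id)
  atlas <- expression_atlas(values[, samples$sample_id, drop = FALSE], tissue_of)

  callus_samples <- samples[samples$tissue == cfg$callus_tissue, , drop = FALSE]
  if (nrow(callus_samples) == 0) {
    stopf("no samples labelled with tissue '%s'", cfg$callus_tissue)
  }
  per_rep <- lapply(callus_samples$sample_id, function(s) {
    top_n_genes(values[, s], cfg$top_n)
  })
  names(per_rep) <- callus_samples$sample_id

  stages <- unique(callus_samples$stage)
  if (any(is.na(stages))) stopf("target-tissue samples need a stage label")
  consensus <- lapply(stages, function(st) {
    stage_consensus(per_rep[callus_samples$sample_id[callus_samples$stage == st]])
  })
  names(consensus) <- stages

  cross <- if (length(consensus) >= 2) {
    cross_stage_intersection(consensus)
  } else {
    consensus[[1]]
  }

  other_tissues <- setdiff(unique(samples$tissue), cfg$callus_tissue)
  specific <- if (length(other_tissues) > 0) {
    tissue_specificity_filter(cross, atlas, cfg)
  } else {
    data.frame(gene_id = character(0), callus_expr = numeric(0),
               max_other_expr = numeric(0), max_other_tissue = character(0),
               ratio = numeric(0), stringsAsFactors = FALSE)
  }
  if (!is.null(de_table)) {
    names(de_table)[1] <- "gene_id"
    specific <- merge(specific, de_table, by = "gene_id",
                      all.x = TRUE, sort = FALSE)
    specific <- specific[order(-specific$callus_expr), , drop = FALSE]
    rownames(specific) <- NULL
  }

  structure(list(
    per_replicate_top = per_rep,
    stage_consensus = consensus,
    cross_stage = cross,
    specific_candidates = specific,
    summary = c(
      stats::setNames(lengths(per_rep), paste0("top_", names(per_rep))),
      stats::setNames(lengths(consensus), paste0("consensus_", names(consensus))),
      cross_stage = length(cross),
      specific = nrow(specific)
    )
  ), class = "screen_result")
}

#' Write a screen result to disk
#'
#' Writes the candidate table as TSV and the per-step set sizes as JSON.
#'
#' @param result A `screen_result` from [run_expression_screen()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$specific_candidates, file.path(dir, "candidates.tsv"))
  jsonlite::write_json(as.list(result$summary),
                       file.path(dir, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
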