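# Relative expression from RT-qPCR cycle thresholds by the 2^-dCt method,
# with technical-then-biological replicate aggregation.

#' Relative expression by the 2^-dCt method
#'
#' `2^-(ct_target - ct_reference)`: one cycle less than the reference doubles
#' the relative expression.
#'
#' @param ct_target,ct_reference Cycle-threshold values (vectorised).
#' @return Positive numeric vector of relative expression levels.
#' @examples
#' relative_expression(25, 20)  # 2^-5 = 0.03125
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stopf("Ct values must be finite")
  }
  2^-(ct_target - ct_reference)
}

#' Mean and sample standard deviation of replicate values
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(mean, sd)`; the SD of a single value is
#'   reported as 0 (with a warning) rather than NA.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) < 1) stopf("need at least one replicate value")
  m <- mean(values)
  s <- if (length(values) == 1) {
    warning("single replicate: SD reported as 0", call. = FALSE)
    0
  } else {
    stats::sd(values)
  }
  c(mean = m, sd = s)
}

#' Relative expression table from a long-format Ct table
#'
#' For every tissue x gene x biological replicate, technical-replicate Ct
#' values are first averaged (separately for target and reference gene),
#' giving one delta-Ct and one `2^-dCt` value per biological replicate; the
#' mean and sample SD are then taken across biological replicates. Set
#' `average_technical = FALSE` to treat every row as its own replicate.
#'
#' @param ct_table data.frame with columns `sample_id`, `tissue`, `gene`,
#'   `replicate_id` (biological replicate), optional `technical_id`, `ct`.
#' @param reference_gene Name of the internal reference gene; reference rows
#'   must exist for every (sample, replicate) used.
#' @param average_technical Average technical replicates within each
#'   biological replicate before aggregation (default TRUE).
#' @return data.frame (tissue, gene, n_replicates, mean_rel_expr,
#'   sd_rel_expr).
#' @export
qpcr_relative_expression <- function(ct_table, reference_gene,
                                     average_technical = TRUE) {
  need <- c("sample_id", "tissue", "gene", "replicate_id", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss) > 0) stopf("ct table missing column(s): %s",
                              paste(miss, collapse = ", "))
  if (any(ct_table$ct <= 0 | !is.finite(ct_table$ct))) {
    stopf("Ct values must be positive and finite")
  }
  if (!reference_gene %in% ct_table$gene) {
    stopf("reference gene '%s' absent from the Ct table", reference_gene)
  }
  ref <- ct_table[ct_table$gene == reference_gene, , drop = FALSE]
  tgt <- ct_table[ct_table$gene != reference_gene, , drop = FALSE]

  # one Ct per (sample, gene, biological replicate)
  collapse <- function(df) {
    if (average_technical) {
      stats::aggregate(ct ~ sample_id + tissue + gene + replicate_id,
                       data = df, FUN = mean)
    } else {
      df[, c("sample_id", "tissue", "gene", "replicate_id", "ct")]
    }
  }
  ref_ct <- collapse(ref)
  tgt_ct <- collapse(tgt)

  key <- function(df) paste(df$sample_id, df$replicate_id, sep = "\r")
  ref_map <- stats::setNames(ref_ct$ct, key(ref_ct))
  ref_here <- ref_map[key(tgt_ct)]
  if (any(is.na(ref_here))) {
    bad <- unique(tgt_ct$sample_id[is.na(ref_here)])
    stopf("no reference-gene Ct for sample/replicate: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  tgt_ct$rel_expr <- relative_expression(tgt_ct$ct, ref_here)

  groups <- split(tgt_ct, list(tgt_ct$tissue, tgt_ct$gene), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    agg <- aggregate_replicates(g$rel_expr)
    data.frame(tissue = g$tissue[1], gene = g$gene[1],
               n_replicates = nrow(g),
               mean_rel_expr = agg[["mean"]], sd_rel_expr = agg[["sd"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$tissue), , drop = FALSE]
}
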