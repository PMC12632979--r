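#' Relative expression by the 2^-ddCt method
#'
#' Computes fold change of a gene in the knockdown condition relative to the
#' control-siRNA condition, each normalized to a reference gene:
#' `2^-[(Ct_gene_kd - Ct_ref_kd) - (Ct_gene_ctrl - Ct_ref_ctrl)]`.
#'
#' All four arguments are recycled to a common length, so replicate vectors
#' can be passed directly.
#'
#' @param ct_gene_kd,ct_ref_kd Cycle thresholds of the target and reference
#'   gene in the knockdown condition.
#' @param ct_gene_ctrl,ct_ref_ctrl Cycle thresholds in the control condition.
#' @return Fold change(s), strictly positive; 1 means no change.
#' @export
relative_expression <- function(ct_gene_kd, ct_ref_kd, ct_gene_ctrl, ct_ref_ctrl) {
  vals <- cbind(ct_gene_kd, ct_ref_kd, ct_gene_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (vals[, 1] - vals[, 2]) - (vals[, 3] - vals[, 4])
  unname(2^(-ddct))
}

#' Knockdown efficiency from replicate fold changes
#'
#' Percent reduction in expression: `100 * (1 - mean(fold changes))`.
#' Replicate fold changes (not ddCt values) are averaged. Negative values
#' indicate expression rose after knockdown.
#'
#' @param fold_changes Numeric vector of replicate 2^-ddCt fold changes.
#' @return Percent knockdown.
#' @export
knockdown_efficiency <- function(fold_changes) {
  if (length(fold_changes) == 0L) stop("at least one fold change is required")
  if (!all(is.finite(fold_changes))) stop("fold changes must be finite")
  100 * (1 - mean(fold_changes))
}

#' Summarize a Ct table into per-gene knockdown efficiencies
#'
#' The table pairs knockdown and control conditions per gene and replicate:
#' columns `gene`, `condition` (`"target_sirna"` / `"control_sirna"`),
#' `replicate`, `ct_gene`, `ct_ref`. Control delta-Ct values are averaged
#' per gene; each knockdown replicate yields one fold change.
#'
#' @param ct_table data.frame as described above.
#' @return data.frame with columns `gene`, `n_replicates`,
#'   `mean_fold_change`, `efficiency_pct`.
#' @export
summarize_knockdown <- function(ct_table) {
  need <- c("gene", "condition", "replicate", "ct_gene", "ct_ref")
  if (!all(need %in% names(ct_table)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(ct_table$condition), c("target_sirna", "control_sirna"))
  if (length(bad) > 0L)
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  res <- lapply(split(ct_table, ct_table$gene), function(g) {
    kd <- g[g$condition == "target_sirna", , drop = FALSE]
    ctrl <- g[g$condition == "control_sirna", , drop = FALSE]
    if (nrow(kd) == 0L || nrow(ctrl) == 0L)
      stop("gene ", g$gene[1], " lacks paired knockdown/control Ct rows")
    dct_ctrl <- mean(ctrl$ct_gene - ctrl$ct_ref)
    folds <- 2^(-((kd$ct_gene - kd$ct_ref) - dct_ctrl))
    data.frame(gene = g$gene[1], n_replicates = nrow(kd),
               mean_fold_change = mean(folds),
               efficiency_pct = knockdown_efficiency(folds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}
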