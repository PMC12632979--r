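#' Quality-control filter on per-sample protein counts
#'
#' Removes samples in which fewer than `min_proteins` proteins were
#' detected (non-missing intensities). The bound is strict: a sample with
#' exactly `min_proteins` detections is retained.
#'
#' @param pm A [protein_matrix()].
#' @param min_proteins Minimum detected proteins per sample. Default 6100.
#' @return List with `matrix` (the filtered [protein_matrix()]) and
#'   `report` (data.frame `sample`, `n_proteins`, `excluded`).
#' @export
qc_filter_samples <- function(pm, min_proteins = 6100L) {
  stopifnot(inherits(pm, "protein_matrix"), min_proteins >= 0L)
  n_det <- colSums(!is.na(pm$intensities))
  excluded <- n_det < min_proteins
  report <- data.frame(sample = colnames(pm$intensities),
                       n_proteins = unname(n_det),
                       excluded = unname(excluded),
                       stringsAsFactors = FALSE)
  if (all(excluded))
    stop("all samples fall below the QC threshold of ", min_proteins,
         " detected proteins")
  keep <- !excluded
  filtered <- protein_matrix(
    pm$intensities[, keep, drop = FALSE],
    pm$metadata[pm$metadata$sample %in% colnames(pm$intensities)[keep], ,
                drop = FALSE]
  )
  list(matrix = filtered, report = report)
}

#' Per-protein one-way ANOVA with Tukey HSD contrasts
#'
#' For one cell line, tests each protein for differential abundance across
#' all siRNA groups (control included) by one-way ANOVA, then computes
#' Tukey HSD adjusted p-values for every target-vs-control pairwise
#' contrast (Tukey-Kramer for unequal group sizes, studentized-range tail
#' areas). Missing intensities are dropped per protein and group
#' (complete-case); groups with fewer than `min_obs` observations are
#' excluded from that protein's ANOVA, and proteins with fewer than two
#' usable groups (or an unusable control) are skipped.
#'
#' The log2 fold change is `mean(target) - mean(control)` on the log2
#' intensity scale. Zero residual variance with unequal means yields an
#' infinite-F record flagged in the output.
#'
#' @param pm A (QC-filtered) [protein_matrix()].
#' @param cell_line Cell line to analyze; groups never span cell lines.
#' @param config A [run_config()] (uses `min_obs_per_group`,
#'   `sig_threshold`).
#' @param control Control siRNA label in the metadata `target` column.
#' @return data.frame with columns `protein`, `cell_line`, `target`,
#'   `log2fc`, `f_stat`, `p_anova`, `p_tukey`, `significant`, `n_target`,
#'   `n_control`, `infinite_f`; the attribute `"skipped"` holds a
#'   data.frame of skipped proteins with reasons.
#' @export
anova_tukey <- function(pm, cell_line, config = run_config(),
                        control = "control") {
  stopifnot(inherits(pm, "protein_matrix"))
  meta <- pm$metadata
  sel <- meta$cell_line == cell_line
  if (!any(sel)) stop("no samples for cell line: ", cell_line)
  X <- pm$intensities[, meta$sample[sel], drop = FALSE]
  grp <- factor(meta$target[sel])
  if (!(control %in% levels(grp)))
    stop("control group '", control, "' absent from cell line ", cell_line)
  min_obs <- config$min_obs_per_group
  glev <- levels(grp)
  k_all <- length(glev)

  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  # proteins x groups summaries
  n_pg <- t(rowsum(t(obs * 1), grp))
  s_pg <- t(rowsum(t(X0), grp))
  q_pg <- t(rowsum(t(X0^2), grp))
  m_pg <- s_pg / n_pg
  m_pg[n_pg == 0] <- 0
  valid <- n_pg >= min_obs

  k_p <- rowSums(valid)
  ctrl_ok <- valid[, control]
  usable <- k_p >= 2L & ctrl_ok
  skipped <- data.frame(
    protein = rownames(X)[!usable],
    reason = ifelse(!ctrl_ok[!usable], "control_below_min_obs",
                    "fewer_than_two_groups"),
    stringsAsFactors = FALSE
  )

  N_p <- rowSums(n_pg * valid)
  ssw_p <- rowSums((q_pg - n_pg * m_pg^2) * valid)
  ssw_p <- pmax(ssw_p, 0)  # guard float negatives
  gbar <- rowSums(s_pg * valid) / N_p
  ssb_p <- rowSums(n_pg * (m_pg - gbar)^2 * valid)
  df_b <- k_p - 1
  df_w <- N_p - k_p
  mse <- ifelse(df_w > 0, ssw_p / df_w, NA_real_)
  msb <- ifelse(df_b > 0, ssb_p / df_b, NA_real_)

  tol <- 1e-10
  zero_var <- !is.na(mse) & mse <= tol
  f_stat <- msb / mse
  f_stat[zero_var & ssb_p <= tol] <- 0
  f_stat[zero_var & ssb_p > tol] <- Inf
  p_anova <- ifelse(is.finite(f_stat),
                    pf(f_stat, df_b, df_w, lower.tail = FALSE),
                    0)
  p_anova[zero_var & ssb_p <= tol] <- 1

  targets <- setdiff(glev, control)
  rows <- lapply(targets, function(tg) {
    ok <- usable & valid[, tg]
    if (!any(ok)) return(NULL)
    d <- m_pg[ok, tg] - m_pg[ok, control]
    n_t <- n_pg[ok, tg]
    n_c <- n_pg[ok, control]
    se_q <- sqrt(mse[ok] / 2 * (1 / n_t + 1 / n_c))
    pt_ <- numeric(sum(ok))
    zv <- zero_var[ok]
    kk <- k_p[ok]
    # k = 2: the studentized range reduces exactly to the pooled t contrast
    two <- !zv & kk == 2L
    pt_[two] <- 2 * pt(abs(d[two]) / (se_q[two] * sqrt(2)),
                       df = df_w[ok][two], lower.tail = FALSE)
    rest <- !zv & kk > 2L
    pt_[rest] <- ptukey(abs(d[rest]) / se_q[rest], nmeans = kk[rest],
                        df = df_w[ok][rest], lower.tail = FALSE)
    pt_[zv] <- ifelse(abs(d[zv]) <= tol, 1, 0)
    data.frame(
      protein = rownames(X)[ok], cell_line = cell_line, target = tg,
      log2fc = unname(d), f_stat = unname(f_stat[ok]),
      p_anova = unname(p_anova[ok]), p_tukey = unname(pt_),
      n_target = unname(n_t), n_control = unname(n_c),
      infinite_f = unname(!is.finite(f_stat[ok])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein = character(), cell_line = character(),
                      target = character(), log2fc = numeric(),
                      f_stat = numeric(), p_anova = numeric(),
                      p_tukey = numeric(), n_target = integer(),
                      n_control = integer(), infinite_f = logical(),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p_tukey <= config$sig_threshold
  out <- out[order(out$target, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Differential abundance across all cell lines
#'
#' Runs [anova_tukey()] separately for every cell line in the metadata
#' and binds the results.
#'
#' @inheritParams anova_tukey
#' @return Combined DE data.frame (see [anova_tukey()]).
#' @export
differential_abundance <- function(pm, config = run_config(),
                                   control = "control") {
  cls <- unique(pm$metadata$cell_line)
  res <- lapply(cls, function(cl) anova_tukey(pm, cl, config, control))
  skipped <- do.call(rbind, lapply(res, attr, "skipped"))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Log2 fold change of the targeted protein in its own knockdown
#'
#' For every target x cell line contrast, extracts the differential
#' abundance of the protein the siRNA was directed against. An effective
#' knockdown shows a negative log2 fold change. Targets whose protein was
#' not quantified are retained with `quantified = FALSE`.
#'
#' @param de DE results from [anova_tukey()] / [differential_abundance()].
#' @param target_map Optional data.frame `target`, `protein` mapping siRNA
#'   targets to protein ids; by default the target id is the protein id.
#' @return data.frame `target`, `cell_line`, `protein`, `log2fc`,
#'   `p_tukey`, `quantified`.
#' @export
target_self_effect <- function(de, target_map = NULL) {
  combos <- unique(de[, c("target", "cell_line")])
  if (is.null(target_map))
    target_map <- data.frame(target = unique(de$target),
                             protein = unique(de$target),
                             stringsAsFactors = FALSE)
  combos$protein <- target_map$protein[match(combos$target, target_map$target)]
  key_de <- paste(de$protein, de$target, de$cell_line, sep = "\r")
  key <- paste(combos$protein, combos$target, combos$cell_line, sep = "\r")
  idx <- match(key, key_de)
  combos$log2fc <- de$log2fc[idx]
  combos$p_tukey <- de$p_tukey[idx]
  combos$quantified <- !is.na(idx) & !is.na(combos$protein)
  rownames(combos) <- NULL
  combos[order(combos$target, combos$cell_line), , drop = FALSE]
}
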