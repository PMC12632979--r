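# Cross-modal integration: assay effect sizes vs term enrichment across
# knockdowns, and the top-tier verdict combining phenotypic hits with
# proteomic disease-signature reversal.

#' Correlate assay effect sizes with term enrichment across knockdowns
#'
#' For each assay and GO term, pairs the mixed-model marginal-mean effect
#' size of every knockdown x cell line with that knockdown's NES for the
#' term, and computes Spearman's rho. LPS-induced assay records (dose
#' other than `"none"`) are excluded before pairing, because the
#' proteomes were collected without induction. P-values are BH-corrected
#' across all tested (assay, term) pairs; pairs with a constant vector on
#' either side are reported untested and excluded from the family.
#'
#' @param effects Assay effects from [assay_effects()].
#' @param enrichments Stacked enrichment results: an [enrich_collection()]
#'   table with added `target` and `cell_line` columns identifying the
#'   knockdown each row came from.
#' @param config A [run_config()] (uses `min_obs_correlation`,
#'   `sig_threshold`).
#' @return data.frame `assay`, `term`, `n_obs`, `rho`, `p`, `p_adj`,
#'   `tested`.
#' @export
phenotype_nes_correlation <- function(effects, enrichments,
                                      config = run_config()) {
  need <- c("target", "cell_line", "set_id", "nes", "nes_defined")
  if (!all(need %in% names(enrichments)))
    stop("enrichments must carry columns: ", paste(need, collapse = ", "))
  eff <- effects[is.na(effects$dose) | effects$dose == "none", , drop = FALSE]
  enr <- enrichments[enrichments$nes_defined, , drop = FALSE]
  ekey <- paste(enr$target, enr$cell_line, sep = "\r")
  rows <- list()
  for (a in unique(eff$assay)) {
    ea <- eff[eff$assay == a, , drop = FALSE]
    akey <- paste(ea$target, ea$cell_line, sep = "\r")
    for (tm in unique(enr$set_id)) {
      et <- enr[enr$set_id == tm, , drop = FALSE]
      idx <- match(akey, paste(et$target, et$cell_line, sep = "\r"))
      ok <- !is.na(idx)
      x <- ea$estimate[ok]
      y <- et$nes[idx[ok]]
      n <- length(x)
      base <- data.frame(assay = a, term = tm, n_obs = n, rho = NA_real_,
                         p = NA_real_, p_adj = NA_real_, tested = FALSE,
                         stringsAsFactors = FALSE)
      if (n >= config$min_obs_correlation && sd(x) > 0 && sd(y) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = FALSE)
        )
        base$rho <- unname(ct$estimate)
        base$p <- ct$p.value
        base$tested <- TRUE
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(assay = character(), term = character(),
                      n_obs = integer(), rho = numeric(), p = numeric(),
                      p_adj = numeric(), tested = logical(),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  out
}

#' Call top-tier targets from dual phenotypic and proteomic evidence
#'
#' The default rule flags a target as top-tier when it has at least one
#' assay hit (any assay, cell line or dose) **and** at least one biodomain
#' whose enrichment signature significantly reverses the disease
#' signature (negative Kendall correlation, any cell line). The hit
#' count, reversal count and the reversal-direction requirement are
#' configurable; tightening any of them can only shrink the set.
#'
#' @param effects Assay effects with `hit` flags from [assay_effects()].
#' @param concordance Domain concordance rows from [domain_kendall()]
#'   (with `target` / `cell_line` columns).
#' @param config A [run_config()] (uses `top_tier_min_hits`,
#'   `top_tier_min_reversals`, `top_tier_require_reversal`,
#'   `sig_threshold`).
#' @return data.frame `target`, `n_hits`, `hit_assays`,
#'   `n_reversal_domains`, `reversal_domains`, `top_tier`, ordered by
#'   target.
#' @export
call_top_tier <- function(effects, concordance, config = run_config()) {
  targets <- sort(union(unique(effects$target),
                        unique(concordance$target)))
  sig <- concordance$tested & !is.na(concordance$p_adj) &
    concordance$p_adj <= config$sig_threshold
  proteomic_ok <- if (config$top_tier_require_reversal) {
    sig & concordance$direction == "reversal"
  } else {
    sig
  }
  rows <- lapply(targets, function(tg) {
    eh <- effects[effects$target == tg & effects$hit, , drop = FALSE]
    hit_assays <- unique(paste(eh$assay, eh$cell_line, sep = ":"))
    cd <- concordance[concordance$target == tg & proteomic_ok, , drop = FALSE]
    rev_doms <- sort(unique(cd$biodomain))
    data.frame(
      target = tg, n_hits = nrow(eh),
      hit_assays = paste(hit_assays, collapse = ";"),
      n_reversal_domains = length(rev_doms),
      reversal_domains = paste(rev_doms, collapse = ";"),
      top_tier = nrow(eh) >= config$top_tier_min_hits &&
        length(rev_doms) >= config$top_tier_min_reversals,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
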