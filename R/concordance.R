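# Disease-signature concordance: zero-imputed NES pairing, per-biodomain
# Kendall rank correlation (tau-b), protein-level Pearson correlation
# through an ortholog map, and quadrant classification of terms.

#' Tie-aware Kendall rank correlation (tau-b)
#'
#' Zero-imputation of enrichment scores produces ties by construction, so
#' the tie-corrected tau-b variant is used: the concordant-minus-discordant
#' pair count normalized by the geometric mean of tie-adjusted pair counts.
#' The two-sided p-value uses the normal approximation with the standard
#' tie-corrected variance of the S statistic.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return List with `tau`, `p`, `n`; `tau` is `NA` (degenerate) when
#'   either vector is constant.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L || anyNA(x) || anyNA(y))
    return(list(tau = NA_real_, p = NA_real_, n = n))
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  tx <- as.numeric(table(x))
  ty <- as.numeric(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  if (n0 - n1 <= 0 || n0 - n2 <= 0)
    return(list(tau = NA_real_, p = NA_real_, n = n))
  tau <- s / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) return(list(tau = tau, p = NA_real_, n = n))
  z <- s / sqrt(var_s)
  list(tau = tau, p = 2 * pnorm(-abs(z)), n = n)
}

#' Pair perturbation and disease enrichment signatures with zero imputation
#'
#' Takes the union of terms significantly enriched (adjusted p at or below
#' the threshold) in either analysis; a term that is non-significant or
#' absent on one side contributes NES 0 there. Terms are annotated with
#' their biodomain(s); a term mapped to several domains appears once per
#' domain.
#'
#' @param results_pert,results_dis Enrichment tables from
#'   [enrich_collection()] over the same term vocabulary.
#' @param biodomain_map data.frame `term_id`, `biodomain`.
#' @param sig_threshold Adjusted-p significance cutoff. Default 0.05.
#' @return data.frame `term`, `biodomain`, `nes_perturbation`,
#'   `nes_disease` (one row per term-domain pairing).
#' @export
zero_impute_pairs <- function(results_pert, results_dis, biodomain_map,
                              sig_threshold = 0.05) {
  sig <- function(res) {
    res$set_id[!is.na(res$p_adj) & res$nes_defined &
                 res$p_adj <= sig_threshold]
  }
  terms <- union(sig(results_pert), sig(results_dis))
  if (length(terms) == 0L) {
    warning("no term is significant in either analysis; empty pair table")
    return(data.frame(term = character(), biodomain = character(),
                      nes_perturbation = numeric(), nes_disease = numeric(),
                      stringsAsFactors = FALSE))
  }
  nes_of <- function(res, term) {
    i <- match(term, res$set_id)
    ok <- !is.na(i) & term %in% sig(res)
    out <- numeric(length(term))
    out[ok] <- res$nes[i[ok]]
    out
  }
  base <- data.frame(term = terms,
                     nes_perturbation = nes_of(results_pert, terms),
                     nes_disease = nes_of(results_dis, terms),
                     stringsAsFactors = FALSE)
  dom <- biodomain_map[biodomain_map$term_id %in% terms, , drop = FALSE]
  unmapped <- setdiff(terms, dom$term_id)
  dom <- rbind(dom, data.frame(term_id = unmapped,
                               biodomain = rep("none", length(unmapped)),
                               stringsAsFactors = FALSE))
  out <- merge(dom, base, by.x = "term_id", by.y = "term")
  names(out)[names(out) == "term_id"] <- "term"
  out <- out[order(out$biodomain, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-biodomain Kendall concordance of paired enrichment signatures
#'
#' Within each biodomain (and any grouping columns `target`, `cell_line`
#' present in the pair table), computes tie-aware Kendall tau-b between
#' the perturbation and disease NES vectors. P-values are BH-corrected
#' across all tested groups in the call; a group is labelled `"reversal"`
#' when significantly negative, `"concordant"` when significantly
#' positive, otherwise `"none"`. Domains with fewer than
#' `min_terms` paired terms, or with a constant vector on either side, are
#' reported untested and excluded from the BH family.
#'
#' @param pair_table Output of [zero_impute_pairs()], optionally with
#'   `target` / `cell_line` columns.
#' @param config A [run_config()] (uses `min_terms_per_domain`,
#'   `sig_threshold`).
#' @return data.frame `target`, `cell_line`, `biodomain`, `n_terms`,
#'   `tau`, `p`, `p_adj`, `direction`, `tested`.
#' @export
domain_kendall <- function(pair_table, config = run_config()) {
  if (!all(c("biodomain", "nes_perturbation", "nes_disease") %in%
             names(pair_table)))
    stop("pair table must have biodomain and paired NES columns")
  if (!"target" %in% names(pair_table)) pair_table$target <- "all"
  if (!"cell_line" %in% names(pair_table)) pair_table$cell_line <- "all"
  grp <- interaction(pair_table$target, pair_table$cell_line,
                     pair_table$biodomain, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(pair_table, grp), function(g) {
    n <- nrow(g)
    base <- data.frame(target = g$target[1], cell_line = g$cell_line[1],
                       biodomain = g$biodomain[1], n_terms = n,
                       tau = NA_real_, p = NA_real_, p_adj = NA_real_,
                       direction = "none", tested = FALSE,
                       stringsAsFactors = FALSE)
    if (n < config$min_terms_per_domain) return(base)
    kt <- kendall_tau_b(g$nes_perturbation, g$nes_disease)
    if (is.na(kt$tau) || is.na(kt$p)) return(base)
    base$tau <- kt$tau
    base$p <- kt$p
    base$tested <- TRUE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  sig <- out$tested & !is.na(out$p_adj) & out$p_adj <= config$sig_threshold
  out$direction[sig & out$tau < 0] <- "reversal"
  out$direction[sig & out$tau > 0] <- "concordant"
  out
}

#' Proteins annotated to each biodomain
#'
#' A protein belongs to a biodomain when it is a member of at least one
#' term annotated to that domain.
#'
#' @param collection A [gene_set_collection()].
#' @param biodomain_map data.frame `term_id`, `biodomain`.
#' @return data.frame `protein`, `biodomain` (unique pairings).
#' @export
protein_biodomains <- function(collection, biodomain_map) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection$sets), function(id) {
    doms <- biodomain_map$biodomain[biodomain_map$term_id == id]
    if (length(doms) == 0L) return(NULL)
    expand.grid(protein = collection$sets[[id]], biodomain = doms,
                stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  if (is.null(out))
    return(data.frame(protein = character(), biodomain = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$biodomain, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-biodomain protein-level Pearson correlation with the disease effect
#'
#' For each target, cell line and biodomain, correlates the knockdown
#' log2 fold changes of the domain's proteins with the disease
#' meta-analysis effect of their orthologs. Proteins with ambiguous
#' (one-to-many) or missing ortholog assignments are dropped and counted.
#' P-values are BH-corrected across all tested combinations in the call.
#'
#' @param de DE results from [differential_abundance()].
#' @param disease_effects data.frame `gene` (disease-side id), `effect`.
#' @param ortholog_map data.frame `protein` (perturbation-side id),
#'   `disease_gene`.
#' @param protein_domains data.frame `protein`, `biodomain` (see
#'   [protein_biodomains()]).
#' @param config A [run_config()] (uses `min_proteins_per_domain`,
#'   `sig_threshold`).
#' @return data.frame `target`, `cell_line`, `biodomain`, `n_proteins`,
#'   `r`, `p`, `p_adj`, `tested`; attribute `"dropped"` counts ambiguous
#'   and unmapped proteins.
#' @export
domain_protein_pearson <- function(de, disease_effects, ortholog_map,
                                   protein_domains, config = run_config()) {
  amb <- names(which(table(ortholog_map$protein) > 1L))
  map <- ortholog_map[!(ortholog_map$protein %in% amb), , drop = FALSE]
  dropped <- data.frame(reason = c("ambiguous_ortholog"),
                        n = length(amb), stringsAsFactors = FALSE)
  dis <- setNames(disease_effects$effect, disease_effects$gene)
  combos <- unique(de[, c("target", "cell_line")])
  doms <- unique(protein_domains$biodomain)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- de[de$target == combos$target[i] &
                de$cell_line == combos$cell_line[i], , drop = FALSE]
    lfc <- setNames(sub$log2fc, sub$protein)
    for (d in doms) {
      prot <- protein_domains$protein[protein_domains$biodomain == d]
      prot <- intersect(prot, names(lfc))
      hg <- map$disease_gene[match(prot, map$protein)]
      ok <- !is.na(hg) & hg %in% names(dis)
      x <- lfc[prot[ok]]
      y <- dis[hg[ok]]
      n <- length(x)
      base <- data.frame(target = combos$target[i],
                         cell_line = combos$cell_line[i], biodomain = d,
                         n_proteins = n, r = NA_real_, p = NA_real_,
                         p_adj = NA_real_, tested = FALSE,
                         stringsAsFactors = FALSE)
      if (n >= config$min_proteins_per_domain && sd(x) > 0 && sd(y) > 0) {
        ct <- stats::cor.test(x, y, method = "pearson")
        base$r <- unname(ct$estimate)
        base$p <- ct$p.value
        base$tested <- TRUE
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  attr(out, "dropped") <- dropped
  out
}

#' Quadrant classification of paired terms
#'
#' Counts, per biodomain (and any `target` / `cell_line` grouping columns),
#' the terms in each sign class of (perturbation NES, disease NES):
#' up/up, down/down, up/down, down/up, and one-sided (zero on either
#' side). Class counts always sum to the number of terms considered.
#'
#' @param pair_table Output of [zero_impute_pairs()].
#' @return data.frame with count columns `up_up`, `down_down`, `up_down`,
#'   `down_up`, `one_sided`, `n_terms`.
#' @export
quadrant_counts <- function(pair_table) {
  if (!"target" %in% names(pair_table)) pair_table$target <- "all"
  if (!"cell_line" %in% names(pair_table)) pair_table$cell_line <- "all"
  grp <- interaction(pair_table$target, pair_table$cell_line,
                     pair_table$biodomain, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(pair_table, grp), function(g) {
    a <- g$nes_perturbation
    b <- g$nes_disease
    data.frame(
      target = g$target[1], cell_line = g$cell_line[1],
      biodomain = g$biodomain[1],
      up_up = sum(a > 0 & b > 0), down_down = sum(a < 0 & b < 0),
      up_down = sum(a > 0 & b < 0), down_up = sum(a < 0 & b > 0),
      one_sided = sum(a == 0 | b == 0), n_terms = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
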