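# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# statistic, gene-label permutation null, sign-stratified normalization.

#' Build a ranked list from a signed statistic
#'
#' Sorts genes by decreasing statistic; ties are broken by gene id so the
#' ordering is deterministic.
#'
#' @param stat Numeric vector of signed ranking statistics (e.g. log2 fold
#'   changes), named by gene, or unnamed with `genes` supplied.
#' @param genes Optional character vector of gene ids.
#' @return Named numeric vector sorted in ranking order.
#' @export
ranked_list <- function(stat, genes = names(stat)) {
  if (is.null(genes)) stop("gene ids are required")
  if (length(genes) != length(stat)) stop("genes and stat lengths differ")
  if (anyDuplicated(genes)) stop("gene ids must be unique in a ranked list")
  if (any(!is.finite(stat))) stop("ranking statistics must be finite")
  ord <- order(-stat, genes)
  setNames(stat[ord], genes[ord])
}

# ES from hit positions in a ranked list.
# absw: |stat|^weight over the full ranked list; pos: sorted hit positions.
# Returns c(es, extreme_index) where extreme_index is the hit index at the
# running-sum extreme (positive ES: leading edge = hits[1:idx]; negative:
# hits[idx:m]).
es_at_positions <- function(absw, pos, n) {
  m <- length(pos)
  w <- absw[pos]
  tw <- sum(w)
  if (tw <= 0) {
    w <- rep(1, m)
    tw <- m
  }
  cumw <- cumsum(w) / tw
  miss <- (pos - seq_len(m)) / (n - m)
  top <- cumw - miss
  bot <- top - w / tw
  imax <- unname(which.max(top))
  imin <- unname(which.min(bot))
  # exact magnitude ties break deterministically toward the positive
  # deviation; the epsilon keeps the choice stable under float rounding
  if (top[imax] >= -bot[imin] - 1e-12) c(unname(top[imax]), imax)
  else c(unname(bot[imin]), imin)
}

#' Running enrichment score of a gene set in a ranked list
#'
#' The classic weighted Kolmogorov-Smirnov preranked statistic: walking
#' down the ranked list, the running sum rises by `|stat|^weight`
#' (normalized over set members) at each set gene and falls by
#' `1/(N - N_hit)` at each non-member. The enrichment score is the signed
#' extreme of this running sum; the leading edge is the set genes at or
#' before the extreme (after, for negative scores).
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of set genes.
#' @param weight Weight exponent on `|stat|`; 0 gives the unweighted KS
#'   statistic. Default 1.
#' @return List with `es` (in \[-1, 1\]), `size` (set genes present in the
#'   ranked list), `leading_edge` (character vector). `NULL` elements and
#'   `size = 0` when the set does not overlap the list.
#' @export
running_es <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  pos <- sort(match(unique(gene_set), genes))
  pos <- pos[!is.na(pos)]
  m <- length(pos)
  if (m == 0L)
    return(list(es = NA_real_, size = 0L, leading_edge = character(0)))
  n <- length(ranked)
  if (m == n) stop("gene set covers the entire ranked list")
  absw <- abs(ranked)^weight
  r <- es_at_positions(absw, pos, n)
  idx <- r[2]
  le <- if (r[1] >= 0) genes[pos[seq_len(idx)]] else genes[pos[idx:m]]
  list(es = r[1], size = m, leading_edge = le)
}

# run code with a private, restored RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# null ES distribution for a set size under gene-label permutation
perm_null_es <- function(absw, n, m, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    es_at_positions(absw, sort(sample.int(n, m)), n)[1]
  }, 0)
}

# NES and p from an observed ES and a permutation null sample.
# NES = ES / mean(|null ES| of the same sign); p uses the add-one
# estimator over same-sign permutations.
nes_p_from_null <- function(es, null_es) {
  same <- if (es >= 0) null_es >= 0 else null_es < 0
  n_same <- sum(same)
  if (n_same == 0L) {
    return(list(nes = NA_real_, p = 1 / (1 + length(null_es)),
                nes_defined = FALSE))
  }
  nes <- es / mean(abs(null_es[same]))
  p <- (1 + sum(abs(null_es[same]) >= abs(es))) / (1 + n_same)
  list(nes = nes, p = p, nes_defined = TRUE)
}

#' Normalized enrichment score and permutation p-value for one set
#'
#' Gene labels are permuted (equivalently, random sets of the same size are
#' drawn from the ranked list) `n_perm` times. The normalized enrichment
#' score divides the observed ES by the mean magnitude of same-sign
#' permutation scores, and the p-value uses the add-one estimator over
#' same-sign permutations, so the smallest attainable p is
#' `1/(1 + n_perm)`. Deterministic given `seed`.
#'
#' @inheritParams running_es
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return List with `es`, `nes`, `p`, `size`, `leading_edge`,
#'   `nes_defined` (`FALSE` when no same-sign permutation exists).
#' @export
nes_and_p <- function(ranked, gene_set, n_perm = 999L, seed = 1L, weight = 1) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  obs <- running_es(ranked, gene_set, weight)
  if (obs$size == 0L)
    return(c(obs, list(nes = NA_real_, p = NA_real_, nes_defined = FALSE)))
  absw <- abs(ranked)^weight
  null_es <- with_local_seed(seed, {
    perm_null_es(absw, length(ranked), obs$size, n_perm)
  })
  c(obs, nes_p_from_null(obs$es, null_es))
}

#' Enrich a whole gene-set collection against a ranked list
#'
#' Applies set-size filters, computes ES/NES/permutation p per set, adjusts
#' p-values by Benjamini-Hochberg across all tested sets in the run, and
#' annotates each term with its biodomain(s) (`"none"` when unmapped).
#' Permutation nulls are shared across sets of identical intersection size
#' (the null depends only on the size), with a deterministic per-size seed
#' derived from `config$seed`.
#'
#' @param ranked A [ranked_list()].
#' @param collection A [gene_set_collection()].
#' @param biodomain_map Optional data.frame `term_id`, `biodomain`.
#' @param config A [run_config()] (uses `min_set_size`, `max_set_size`,
#'   `n_perm`, `gsea_weight`, `seed`).
#' @return data.frame with columns `set_id`, `size`, `es`, `nes`, `p`,
#'   `p_adj`, `nes_defined`, `biodomains`, `leading_edge`; attribute
#'   `"skipped"` records filtered sets and reasons.
#' @export
enrich_collection <- function(ranked, collection, biodomain_map = NULL,
                              config = run_config()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- names(ranked)
  weight <- config$gsea_weight
  absw <- abs(ranked)^weight
  n <- length(ranked)

  sizes <- vapply(collection$sets, function(s) sum(unique(s) %in% genes), 0L)
  reason <- rep(NA_character_, length(sizes))
  reason[sizes == 0L] <- "no overlap"
  reason[sizes > 0L & sizes < config$min_set_size] <- "below min size"
  reason[sizes > config$max_set_size] <- "above max size"
  keep <- is.na(reason)
  skipped <- data.frame(set_id = names(collection$sets)[!keep],
                        size = unname(sizes[!keep]),
                        reason = reason[!keep], stringsAsFactors = FALSE)
  empty <- data.frame(set_id = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), p_adj = numeric(),
                      nes_defined = logical(), biodomains = character(),
                      leading_edge = character(), stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("all gene sets were filtered out")
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  ids <- names(collection$sets)[keep]
  usz <- sort(unique(sizes[keep]))
  nulls <- lapply(usz, function(m) {
    with_local_seed(config$seed + m, perm_null_es(absw, n, m, config$n_perm))
  })
  names(nulls) <- as.character(usz)

  rows <- lapply(ids, function(id) {
    obs <- running_es(ranked, collection$sets[[id]], weight)
    np <- nes_p_from_null(obs$es, nulls[[as.character(obs$size)]])
    data.frame(set_id = id, size = obs$size, es = obs$es, nes = np$nes,
               p = np$p, nes_defined = np$nes_defined,
               leading_edge = paste(obs$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  if (is.null(biodomain_map) || nrow(biodomain_map) == 0L) {
    out$biodomains <- "none"
  } else {
    dom <- vapply(out$set_id, function(id) {
      d <- biodomain_map$biodomain[biodomain_map$term_id == id]
      if (length(d) == 0L) "none" else paste(sort(d), collapse = ",")
    }, "")
    out$biodomains <- unname(dom)
  }
  out <- out[, c("set_id", "size", "es", "nes", "p", "p_adj", "nes_defined",
                 "biodomains", "leading_edge")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Ranked list from differential-abundance results
#'
#' Extracts the per-protein log2 fold change for one target and cell line
#' as a ranking statistic.
#'
#' @param de DE results from [differential_abundance()].
#' @param target,cell_line Contrast to extract.
#' @return A [ranked_list()].
#' @export
ranked_from_de <- function(de, target, cell_line) {
  rows <- de[de$target == target & de$cell_line == cell_line, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no DE rows for target ", target, " in cell line ", cell_line)
  ranked_list(rows$log2fc, rows$protein)
}
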