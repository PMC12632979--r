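# Independent brute-force oracles. These deliberately use the most direct
# (slow) formulation of each statistic so they share no code path with the
# package implementations they check.

# step-up FDR adjustment, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m))
  }
  pmin(adj, 1)[order(ord)]
}

# enrichment score by walking the full running sum, position by position
oracle_es <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n <- length(ranked)
  m <- sum(hit)
  w <- abs(ranked)^weight
  tw <- sum(w[hit])
  if (tw <= 0) {
    w[hit] <- 1
    tw <- m
  }
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) w[i] / tw else -1 / (n - m)
    running[i] <- cur
  }
  # small epsilon keeps the positive-side tie-break stable under the
  # accumulated floating error of the position-by-position walk
  if (max(running) >= -min(running) - 1e-9) max(running) else min(running)
}

# tau-b by explicit pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Spearman rho: midranks, then the Pearson formula on the ranks
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}
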