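test_that("tau-b hits the extremes on identical and negated vectors", {
  x <- c(0.5, 2.1, -1, 3, 0.2, 1.1)
  expect_equal(kendall_tau_b(x, x)$tau, 1)
  expect_equal(kendall_tau_b(x, -x)$tau, -1)
  expect_true(is.na(kendall_tau_b(x, rep(1, 6))$tau))
  expect_error(kendall_tau_b(x, x[1:3]), "equal length")
})

test_that("tau-b matches brute-force pair counting and cor.test under ties", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    # mix continuous values with zeros to force ties, as zero-imputation does
    x <- ifelse(runif(n) < 0.3, 0, round(rnorm(n), 1))
    y <- ifelse(runif(n) < 0.3, 0, round(rnorm(n), 1))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- kendall_tau_b(x, y)
    expect_equal(mine$tau, oracle_kendall(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
    expect_equal(mine$tau, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-8)
  }
})

make_enr <- function(ids, nes, p_adj) {
  data.frame(set_id = ids, size = 20L, es = sign(nes) * 0.5, nes = nes,
             p = p_adj, p_adj = p_adj, nes_defined = TRUE,
             biodomains = "none", leading_edge = "",
             stringsAsFactors = FALSE)
}

test_that("zero imputation keeps the union of significant terms", {
  bm <- data.frame(term_id = c("T1", "T2", "T3"),
                   biodomain = rep("Synapse", 3), stringsAsFactors = FALSE)
  a <- make_enr(c("T1", "T2"), c(2.1, 1.0), c(0.01, 0.5))
  b <- make_enr(c("T2", "T3"), c(-1.5, 2.4), c(0.9, 0.02))
  pairs <- zero_impute_pairs(a, b, bm, 0.05)
  # T1 significant only in A: disease side imputed to 0
  expect_equal(pairs[pairs$term == "T1", "nes_perturbation"], 2.1)
  expect_equal(pairs[pairs$term == "T1", "nes_disease"], 0)
  # T3 significant only in B
  expect_equal(pairs[pairs$term == "T3", "nes_perturbation"], 0)
  expect_equal(pairs[pairs$term == "T3", "nes_disease"], 2.4)
  # T2 non-significant in both: excluded from the union
  expect_false("T2" %in% pairs$term)
  # both empty: warning and empty table
  none <- make_enr("T1", 1, 0.9)
  expect_warning(empty <- zero_impute_pairs(none, none, bm, 0.05), "no term")
  expect_equal(nrow(empty), 0L)
})

test_that("pair counts per domain match a hand count on a 12-term fixture", {
  set.seed(73)
  ids <- sprintf("T%02d", 1:12)
  doms <- rep(c("Synapse", "Apoptosis", "DNA Repair"), each = 4)
  bm <- data.frame(term_id = ids, biodomain = doms, stringsAsFactors = FALSE)
  a <- make_enr(ids, rnorm(12), rep(c(0.01, 0.5), 6))
  b <- make_enr(ids, rnorm(12), rep(c(0.5, 0.5, 0.01), 4))
  pairs <- zero_impute_pairs(a, b, bm, 0.05)
  union_ids <- union(ids[rep(c(TRUE, FALSE), 6)],
                     ids[rep(c(FALSE, FALSE, TRUE), 4)])
  expect_setequal(pairs$term, union_ids)
  for (d in unique(doms)) {
    expect_equal(sum(pairs$biodomain == d),
                 length(intersect(union_ids, ids[doms == d])))
  }
  # a term mapped to two domains appears once per domain
  bm2 <- rbind(bm, data.frame(term_id = "T01", biodomain = "Epigenetic"))
  pairs2 <- zero_impute_pairs(a, b, bm2, 0.05)
  expect_equal(sum(pairs2$term == "T01"), 2L)
})

test_that("domain-level Kendall labels reversals and respects the BH family", {
  nes <- seq(-2.5, 2.5, length.out = 8)
  pt <- rbind(
    data.frame(term = sprintf("a%d", 1:8), biodomain = "Synapse",
               nes_perturbation = nes, nes_disease = nes * 1.3,
               stringsAsFactors = FALSE),
    data.frame(term = sprintf("b%d", 1:8), biodomain = "Apoptosis",
               nes_perturbation = nes, nes_disease = -nes,
               stringsAsFactors = FALSE),
    data.frame(term = sprintf("c%d", 1:3), biodomain = "DNA Repair",
               nes_perturbation = nes[1:3], nes_disease = nes[1:3],
               stringsAsFactors = FALSE),
    data.frame(term = sprintf("d%d", 1:8), biodomain = "Epigenetic",
               nes_perturbation = rep(0, 8), nes_disease = nes,
               stringsAsFactors = FALSE)
  )
  dk <- domain_kendall(pt, run_config(min_terms_per_domain = 5))
  syn <- dk[dk$biodomain == "Synapse", ]
  apo <- dk[dk$biodomain == "Apoptosis", ]
  expect_equal(syn$tau, 1)
  expect_equal(syn$direction, "concordant")
  expect_equal(apo$tau, -1)
  expect_equal(apo$direction, "reversal")
  # below the minimum term count: reported untested
  expect_false(dk$tested[dk$biodomain == "DNA Repair"])
  # constant perturbation side: degenerate, untested, excluded from BH
  expect_false(dk$tested[dk$biodomain == "Epigenetic"])
  expect_equal(sum(dk$tested), 2L)
})

test_that("protein-level Pearson matches the covariance formula and maps orthologs", {
  prot <- sprintf("P%02d", 1:8)
  lfc <- c(0.4, -1.2, 0.8, 2.0, -0.5, 1.1, -2.2, 0.3)
  de <- data.frame(protein = prot, cell_line = "cl1", target = "t1",
                   log2fc = lfc, f_stat = 1, p_anova = 0.5, p_tukey = 0.5,
                   n_target = 4L, n_control = 4L, infinite_f = FALSE,
                   significant = FALSE, stringsAsFactors = FALSE)
  orth <- data.frame(protein = prot, disease_gene = paste0("H", prot),
                     stringsAsFactors = FALSE)
  pdom <- data.frame(protein = prot, biodomain = "Synapse",
                     stringsAsFactors = FALSE)
  cfg <- run_config(min_proteins_per_domain = 5)
  # proportional disease effect: perfect concordance
  dis <- data.frame(gene = paste0("H", prot), effect = 2 * lfc,
                    stringsAsFactors = FALSE)
  r1 <- domain_protein_pearson(de, dis, orth, pdom, cfg)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  # negated: perfect reversal
  dis$effect <- -lfc
  r2 <- domain_protein_pearson(de, dis, orth, pdom, cfg)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  # generic vector: matches the direct covariance formula
  set.seed(79)
  dis$effect <- rnorm(8)
  r3 <- domain_protein_pearson(de, dis, orth, pdom, cfg)
  expect_equal(r3$r, oracle_pearson(lfc, dis$effect), tolerance = 1e-12)
  # an ambiguous ortholog drops the protein and is counted
  orth2 <- rbind(orth, data.frame(protein = "P01", disease_gene = "Hother"))
  r4 <- domain_protein_pearson(de, dis, orth2, pdom, cfg)
  expect_equal(r4$n_proteins, 7L)
  expect_equal(attr(r4, "dropped")$n, 1L)
  expect_equal(r4$r, oracle_pearson(lfc[-1], dis$effect[-1]),
               tolerance = 1e-12)
})

test_that("quadrant counts classify sign patterns and sum to the term count", {
  pt <- data.frame(
    term = sprintf("t%d", 1:6), biodomain = "Synapse",
    nes_perturbation = c(1, -1, 2, -2, 0, 1.5),
    nes_disease = c(2, -2, -1, 1, 3, 0),
    stringsAsFactors = FALSE
  )
  qc <- quadrant_counts(pt)
  expect_equal(qc$up_up, 1L)
  expect_equal(qc$down_down, 1L)
  expect_equal(qc$up_down, 1L)
  expect_equal(qc$down_up, 1L)
  expect_equal(qc$one_sided, 2L)
  expect_equal(qc$up_up + qc$down_down + qc$up_down + qc$down_up +
                 qc$one_sided, qc$n_terms)
  # all disease-side zeros: everything is one-sided
  pt$nes_disease <- 0
  qc2 <- quadrant_counts(pt)
  expect_equal(qc2$one_sided, 6L)
})

test_that("swapping analyses transposes quadrants and preserves |tau|", {
  set.seed(83)
  pt <- data.frame(
    term = sprintf("t%d", 1:12), biodomain = "Synapse",
    nes_perturbation = ifelse(runif(12) < 0.25, 0, rnorm(12)),
    nes_disease = ifelse(runif(12) < 0.25, 0, rnorm(12)),
    stringsAsFactors = FALSE
  )
  swapped <- pt
  swapped$nes_perturbation <- pt$nes_disease
  swapped$nes_disease <- pt$nes_perturbation
  q1 <- quadrant_counts(pt)
  q2 <- quadrant_counts(swapped)
  expect_equal(q1$up_down, q2$down_up)
  expect_equal(q1$down_up, q2$up_down)
  expect_equal(q1$up_up, q2$up_up)
  k1 <- kendall_tau_b(pt$nes_perturbation, pt$nes_disease)
  k2 <- kendall_tau_b(swapped$nes_perturbation, swapped$nes_disease)
  expect_equal(abs(k1$tau), abs(k2$tau), tolerance = 1e-12)
})
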