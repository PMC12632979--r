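test_that("the QC filter uses a strict fewer-than rule and reports exclusions", {
  set.seed(3)
  n <- 7000
  X <- matrix(rnorm(n * 3, 25, 2), n,
              dimnames = list(sprintf("p%04d", 1:n), c("s1", "s2", "s3")))
  X[1:(n - 565), 1] <- NA       # degraded sample: 565 detections
  X[1:(n - 6100), 2] <- NA      # exactly at the threshold: retained
  pm <- toy_protein_matrix(X, targets = c("t1", "t1", "control"))
  qc <- qc_filter_samples(pm, min_proteins = 6100)
  expect_equal(qc$report$n_proteins, c(565L, 6100L, 7000L))
  expect_equal(qc$report$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(colnames(qc$matrix$intensities), c("s2", "s3"))
  expect_error(qc_filter_samples(pm, min_proteins = 10000), "all samples")
})

test_that("QC retention matches a direct count oracle on dropout data", {
  sim <- tiny_sim()
  counts <- colSums(!is.na(sim$proteome$intensities))
  qc <- qc_filter_samples(sim$proteome, 240)
  expect_equal(ncol(qc$matrix$intensities), sum(counts >= 240))
  expect_equal(sum(qc$report$excluded), sum(counts < 240))
})

test_that("identical groups give F = 0 and all pairwise p = 1", {
  X <- matrix(rep(c(5, 7, 9), each = 9), nrow = 3, byrow = TRUE)
  pm <- toy_protein_matrix(X, targets = rep(c("control", "t1", "t2"), 3))
  de <- anova_tukey(pm, "cl1")
  expect_equal(de$f_stat, rep(0, nrow(de)))
  expect_equal(de$p_tukey, rep(1, nrow(de)))
  expect_equal(de$log2fc, rep(0, nrow(de)))
})

test_that("ANOVA F matches the textbook sums-of-squares formula", {
  x <- c(1, 2, 3, 6, 7, 8, 11, 12, 13)
  g <- rep(c("control", "t1", "t2"), each = 3)
  X <- matrix(x, nrow = 1)
  pm <- toy_protein_matrix(X, targets = g)
  de <- anova_tukey(pm, "cl1")
  gm <- mean(x)
  ssb <- sum(3 * (tapply(x, g, mean) - gm)^2)
  ssw <- sum((x - rep(tapply(x, g, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(unique(de$f_stat), f_hand, tolerance = 1e-10)
})

test_that("ANOVA and Tukey p-values match aov/TukeyHSD on random instances", {
  set.seed(17)
  for (i in 1:15) {
    k <- sample(3:5, 1)
    n_per <- sample(3:6, 1)
    g <- rep(c("control", paste0("t", seq_len(k - 1))), each = n_per)
    x <- rnorm(length(g), 20, 1) + rep(rnorm(k, 0, 0.5), each = n_per)
    pm <- toy_protein_matrix(matrix(x, nrow = 1), targets = g)
    de <- anova_tukey(pm, "cl1")
    fit <- aov(x ~ factor(g))
    expect_equal(unique(de$f_stat), unname(summary(fit)[[1]]$`F value`[1]),
                 tolerance = 1e-8)
    tk <- TukeyHSD(fit)$`factor(g)`
    for (j in seq_len(nrow(de))) {
      row <- paste0(de$target[j], "-control")
      expect_equal(de$p_tukey[j], tk[row, "p adj"], tolerance = 1e-6)
      expect_equal(de$log2fc[j], tk[row, "diff"], tolerance = 1e-10)
    }
  }
})

test_that("Tukey with two groups reduces to the pooled two-sample comparison", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- c(rnorm(n1, 20), rnorm(n2, 20.5))
    g <- rep(c("control", "t1"), c(n1, n2))
    pm <- toy_protein_matrix(matrix(x, nrow = 1), targets = g)
    de <- anova_tukey(pm, "cl1")
    tt <- t.test(x[g == "t1"], x[g == "control"], var.equal = TRUE)
    expect_equal(de$p_tukey, tt$p.value, tolerance = 1e-8)
  }
})

test_that("Tukey-adjusted p dominates the same contrast without adjustment", {
  set.seed(29)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    n_per <- 4
    g <- rep(c("control", paste0("t", seq_len(k - 1))), each = n_per)
    x <- rnorm(length(g), 20, 1)
    pm <- toy_protein_matrix(matrix(x, nrow = 1), targets = g)
    de <- anova_tukey(pm, "cl1")
    # unadjusted p of the same contrast: pooled MSE over all k groups
    fit <- aov(x ~ factor(g))
    mse <- summary(fit)[[1]]$`Mean Sq`[2]
    dfw <- fit$df.residual
    for (j in seq_len(nrow(de))) {
      d <- mean(x[g == de$target[j]]) - mean(x[g == "control"])
      t_stat <- abs(d) / sqrt(mse * 2 / n_per)
      p_unadj <- 2 * pt(-t_stat, dfw)
      expect_gte(de$p_tukey[j] + 1e-12, p_unadj)
    }
  }
})

test_that("missing values are handled complete-case with a min-obs gate", {
  X <- matrix(rnorm(30, 20), nrow = 3)
  X[1, 1:3] <- NA  # control group of protein 1 drops to 2 observations
  X[2, 6:10] <- NA # both target groups of protein 2 vanish
  g <- rep(c("control", "t1"), each = 5)
  pm <- toy_protein_matrix(X, targets = g)
  de <- anova_tukey(pm, "cl1", run_config(min_obs_per_group = 3))
  skipped <- attr(de, "skipped")
  expect_setequal(de$protein, "P003")
  expect_setequal(skipped$protein, c("P001", "P002"))
  expect_equal(skipped$reason[skipped$protein == "P001"],
               "control_below_min_obs")
})

test_that("zero residual variance with unequal means yields a flagged infinite F", {
  X <- matrix(rep(c(1, 1, 1, 2, 2, 2), 2), nrow = 2, byrow = TRUE)
  pm <- toy_protein_matrix(X, targets = rep(c("control", "t1"), each = 3))
  de <- anova_tukey(pm, "cl1")
  expect_true(all(de$infinite_f))
  expect_equal(de$p_tukey, c(0, 0))
  expect_equal(de$log2fc, c(1, 1))
})

test_that("swapping the contrast direction negates the log2 fold change", {
  set.seed(41)
  x <- rnorm(12, 20)
  pm_a <- toy_protein_matrix(matrix(x, nrow = 1),
                             targets = rep(c("control", "t1"), each = 6))
  pm_b <- toy_protein_matrix(matrix(x, nrow = 1),
                             targets = rep(c("t1", "control"), each = 6))
  de_a <- anova_tukey(pm_a, "cl1")
  de_b <- anova_tukey(pm_b, "cl1")
  expect_equal(de_a$log2fc, -de_b$log2fc, tolerance = 1e-12)
  expect_equal(de_a$p_tukey, de_b$p_tukey, tolerance = 1e-12)
})

test_that("the targeted protein shows a negative fold change in its own knockdown", {
  sim <- tiny_sim()
  qc <- qc_filter_samples(sim$proteome, 240)
  de <- differential_abundance(qc$matrix, tiny_run_config())
  tse <- target_self_effect(de)
  expect_true(all(tse$log2fc[tse$quantified] < 0))
  # a target whose protein is absent from the matrix is recorded, not dropped
  tse2 <- target_self_effect(
    de, target_map = data.frame(target = unique(de$target),
                                protein = "NOT_A_PROTEIN"))
  expect_true(all(!tse2$quantified))
  expect_equal(nrow(tse2), nrow(tse))
})

test_that("noise-free proteomes recover exactly the planted significant set", {
  # with exactly zero noise the planted contrasts are infinite-F records
  # and every unplanted contrast is a constant-group p = 1 record
  cfg <- tiny_sim_config(seed = 13, proteome_residual_sd = 0,
                         dropout_rate = 0, n_bad_samples = 0L)
  ann <- generate_annotation(cfg)
  truth <- make_synthetic_truth(cfg, ann)
  pm <- generate_knockdown_proteomes(cfg, ann, truth)
  de <- differential_abundance(pm, tiny_run_config())
  planted <- truth$targets[truth$targets$role == "dual", ]
  doms <- strsplit(planted$planted_domains, ";")[[1]]
  shifted <- ann$gene_domains$gene[ann$gene_domains$domain %in% doms]
  shifted <- union(shifted, planted$target)
  for (cl in cfg$cell_lines) {
    sig <- de$protein[de$significant & de$target == planted$target &
                        de$cell_line == cl]
    expect_setequal(sig, shifted)
  }
})
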