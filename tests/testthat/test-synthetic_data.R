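test_that("simulation configs validate their invariants", {
  expect_error(simulation_config(n_targets = 0), "at least 1")
  expect_error(simulation_config(dropout_rate = 1), "dropout")
  expect_error(simulation_config(batch_sd = -1), "non-negative")
  expect_error(simulation_config(n_planted_dual = 50), "exceed")
  expect_error(simulation_config(term_size_range = c(10, 5)), "increasing")
  # term sizes infeasible for the per-domain pool
  expect_error(simulation_config(n_proteins = 60, term_size_range = c(5, 40)),
               "infeasible")
  expect_error(simulation_config(domains = c("Synapse", "Narnia")),
               "vocabulary")
})

test_that("annotation respects sizes, per-domain allocation and determinism", {
  cfg <- tiny_sim_config()
  ann <- generate_annotation(cfg)
  sizes <- lengths(ann$collection$sets)
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_equal(length(ann$collection), 30L)
  # terms allocated to domains as evenly as possible (30 over 6 = 5 each)
  expect_equal(unname(table(ann$biodomain_map$biodomain)[cfg$domains]),
               rep(5L, 6), ignore_attr = TRUE)
  # every term maps to exactly one domain, drawn from the pool of that domain
  expect_equal(anyDuplicated(ann$biodomain_map$term_id), 0L)
  pool <- split(ann$gene_domains$gene, ann$gene_domains$domain)
  for (i in seq_len(10)) {
    id <- names(ann$collection$sets)[i]
    d <- ann$biodomain_map$biodomain[ann$biodomain_map$term_id == id]
    expect_true(all(ann$collection$sets[[id]] %in% pool[[d]]))
  }
  ann2 <- generate_annotation(cfg)
  expect_identical(ann, ann2)
})

test_that("disease effects follow the planted domain directions", {
  cfg <- tiny_sim_config()
  ann <- generate_annotation(cfg)
  truth <- make_synthetic_truth(cfg, ann)
  dis <- generate_disease_effects(cfg, ann, truth)
  gd <- ann$gene_domains
  eff <- setNames(dis$effect, sub("^H", "", dis$gene))
  up <- eff[gd$gene[gd$domain %in% cfg$disease_up_domains]]
  dn <- eff[gd$gene[gd$domain %in% cfg$disease_down_domains]]
  expect_gt(mean(up), 0.5)
  expect_lt(mean(dn), -0.5)
  # zero involvement SD collapses every gene onto its domain mean
  cfg0 <- tiny_sim_config(disease_effect_sd = 0)
  truth0 <- make_synthetic_truth(cfg0, generate_annotation(cfg0))
  w0 <- truth0$gene_involvement
  expect_true(all(w0$involvement[w0$disease_direction == 1] == 1))
  expect_true(all(w0$involvement[w0$disease_direction == -1] == -1))
  expect_true(all(w0$involvement[w0$disease_direction == 0] == 0))
})

test_that("noise-free proteomes carry exactly the planted group shifts", {
  cfg <- tiny_sim_config(proteome_residual_sd = 0, dropout_rate = 0,
                         n_bad_samples = 0L)
  ann <- generate_annotation(cfg)
  truth <- make_synthetic_truth(cfg, ann)
  pm <- generate_knockdown_proteomes(cfg, ann, truth)
  X <- pm$intensities
  meta <- pm$metadata
  dual <- truth$targets[truth$targets$role == "dual", ]
  doms <- strsplit(dual$planted_domains, ";")[[1]]
  w <- setNames(truth$gene_involvement$involvement,
                truth$gene_involvement$gene)
  for (cl in cfg$cell_lines) {
    mult <- if (cl == cfg$cell_lines[2]) cfg$sensitization_multiplier else 1
    kd <- rowMeans(X[, meta$cell_line == cl & meta$target == dual$target])
    ctrl <- rowMeans(X[, meta$cell_line == cl & meta$target == "control"])
    delta <- kd - ctrl
    in_dom <- ann$gene_domains$domain %in% doms
    expected <- setNames(ifelse(in_dom, -cfg$reversal_scale * w * mult, 0),
                         ann$gene_domains$gene)
    expected[dual$target] <- expected[dual$target] + cfg$knockdown_lfc * mult
    expect_equal(unname(delta), unname(expected), tolerance = 1e-10)
  }
})

test_that("the targeted protein is depleted in its own knockdown samples", {
  sim <- tiny_sim()
  X <- sim$proteome$intensities
  meta <- sim$proteome$metadata
  for (tg in sim$truth$targets$target) {
    own <- mean(X[tg, meta$target == tg], na.rm = TRUE)
    ctrl <- mean(X[tg, meta$target == "control"], na.rm = TRUE)
    expect_lt(own, ctrl)
  }
})

test_that("dropout fraction tracks the configured rate", {
  cfg <- simulation_config(n_targets = 2L, n_proteins = 2000L,
                           n_terms = 10L, term_size_range = c(5L, 20L),
                           n_planted_dual = 1L, n_planted_assay_only = 0L,
                           replicates_per_group = 3L,
                           dropout_rate = 0.1, n_bad_samples = 0L, seed = 3L)
  ann <- generate_annotation(cfg)
  truth <- make_synthetic_truth(cfg, ann)
  pm <- generate_knockdown_proteomes(cfg, ann, truth)
  expect_lt(abs(mean(is.na(pm$intensities)) - 0.1), 0.02)
})

test_that("noise-free assay batches reproduce planted effects exactly", {
  cfg <- tiny_sim_config(batch_sd = 0, assay_noise_sd = 0)
  ann <- generate_annotation(cfg)
  truth <- make_synthetic_truth(cfg, ann)
  tab <- generate_assay_data(cfg, truth)
  lfc <- batch_log2fc(tab)
  key <- function(d) paste(d$target, d$assay, d$cell_line, d$dose)
  planted <- truth$assay_effects$effect[
    match(key(lfc), key(truth$assay_effects))]
  expect_equal(lfc$log2fc, planted, tolerance = 1e-10)
})

test_that("between-batch spread grows with the configured batch SD", {
  spread <- vapply(c(0, 0.3, 0.9), function(bsd) {
    cfg <- tiny_sim_config(batch_sd = bsd, assay_noise_sd = 0.01, seed = 5L)
    truth <- make_synthetic_truth(cfg, generate_annotation(cfg))
    tab <- generate_assay_data(cfg, truth)
    one <- tab[tab$assay == "mitotracker" & tab$cell_line == "scramble", ]
    sd(log2(tapply(one$readout, one$batch, mean)))
  }, 0)
  expect_true(all(diff(spread) > 0))
})

test_that("generators are deterministic and the written screen is byte-stable", {
  cfg <- tiny_sim_config(seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_screen(cfg, d1)
  s2 <- simulate_screen(cfg, d2)
  expect_identical(s1$assay_table, s2$assay_table)
  expect_identical(s1$proteome, s2$proteome)
  for (f in names(s1$files)) {
    expect_identical(unname(tools::md5sum(s1$files[[f]])),
                     unname(tools::md5sum(s2$files[[f]])),
                     label = paste("md5 of", f))
  }
  # and a different seed changes the data
  s3 <- simulate_screen(tiny_sim_config(seed = 20))
  expect_false(identical(s1$assay_table$readout, s3$assay_table$readout))
})

test_that("written synthetic inputs are read back identically by the io layer", {
  cfg <- tiny_sim_config(seed = 23)
  dir <- withr::local_tempdir()
  sim <- simulate_screen(cfg, dir)
  expect_identical(read_gmt(file.path(dir, "gene_sets.gmt")),
                   sim$annotation$collection)
  bm <- read_biodomain_map(file.path(dir, "biodomain_map.tsv"))
  expect_equal(bm, sim$annotation$biodomain_map, ignore_attr = TRUE)
  pm <- read_protein_matrix(file.path(dir, "protein_matrix.tsv"),
                            file.path(dir, "protein_metadata.tsv"))
  expect_equal(pm$intensities, sim$proteome$intensities, tolerance = 1e-12)
  expect_identical(is.na(pm$intensities), is.na(sim$proteome$intensities))
})
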