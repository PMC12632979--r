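# Shared fixtures: a small synthetic screen sized for fast tests, built
# once per test run.

tiny_sim_config <- function(seed = 7L, ...) {
  defaults <- list(
    n_targets = 4L, n_proteins = 300L, n_terms = 30L,
    term_size_range = c(5L, 15L), n_planted_dual = 1L,
    n_planted_assay_only = 1L, replicates_per_group = 4L,
    n_bad_samples = 1L, seed = seed
  )
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

tiny_run_config <- function(seed = 7L, ...) {
  run_config(qc_min_proteins = 240L, n_perm = 199L, min_set_size = 5L,
             seed = seed, ...)
}

.tiny_sim_cache <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.tiny_sim_cache$sim))
    .tiny_sim_cache$sim <- simulate_screen(tiny_sim_config())
  .tiny_sim_cache$sim
}

# a small deterministic assay table built by hand
toy_assay_table <- function(target_reps, control_reps,
                            assay = "a1", cell_line = "cl1",
                            dose = "none", batch = "b1") {
  rbind(
    data.frame(assay = assay, target = "tgt", cell_line = cell_line,
               dose = dose, batch = batch,
               replicate = as.character(seq_along(target_reps)),
               readout = target_reps, stringsAsFactors = FALSE),
    data.frame(assay = assay, target = "control", cell_line = cell_line,
               dose = dose, batch = batch,
               replicate = as.character(seq_along(control_reps)),
               readout = control_reps, stringsAsFactors = FALSE)
  )
}

# protein matrix from a plain matrix, with minimal metadata
toy_protein_matrix <- function(X, targets, cell_line = "cl1") {
  if (is.null(rownames(X))) rownames(X) <- sprintf("P%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("s%03d", seq_len(ncol(X)))
  protein_matrix(X, data.frame(
    sample = colnames(X), target = targets,
    cell_line = rep(cell_line, length.out = ncol(X)),
    replicate = as.character(seq_len(ncol(X))),
    stringsAsFactors = FALSE
  ))
}
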