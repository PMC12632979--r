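# Pipeline orchestration: one entry point wiring config, seeds and stage
# outputs. Stages communicate only through documented TSV/CSV/GMT files
# under the run directory, so any stage can be re-run from the files of
# the previous one.

#' Reference configurations for the synthetic screen
#'
#' The package's reference study conditions: the default
#' [simulation_config()] (12 targets, 2 cell lines, 4 assays, 2,000
#' proteins, 100 terms over 6 domains, 3 planted dual-evidence targets)
#' paired with a [run_config()] whose QC threshold (1,600 detected
#' proteins) and permutation count (999) are scaled to that data set.
#'
#' @param seed Integer seed applied to both configurations.
#' @return List with elements `sim` and `run`.
#' @export
synthetic_reference_configs <- function(seed = 1L) {
  list(
    sim = simulation_config(seed = seed),
    run = run_config(qc_min_proteins = 1600L, n_perm = 999L, seed = seed)
  )
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, out_dir, code) {
  tryCatch(force(code), error = function(e) {
    writeLines(stage, file.path(out_dir, ".failed_stage"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Chains simulate, knockdown QC, phenotype hit calling, proteomic
#' differential abundance, enrichment (knockdown and disease sides),
#' concordance and integration from one pair of configurations. Every
#' stage writes its outputs under `out_dir` and subsequent stages read
#' only those files. A JSON run manifest with the seed and per-file MD5
#' checksums is written last; re-running with an identical configuration
#' reproduces identical checksums.
#'
#' @param sim_config A [simulation_config()].
#' @param config A [run_config()] scaled to the simulated data (see
#'   [synthetic_reference_configs()]).
#' @param out_dir Run directory (created if needed).
#' @return The manifest, invisibly (list with `seed`, `config_hash`,
#'   `stages`, `files`).
#' @export
run_all <- function(sim_config = synthetic_reference_configs()$sim,
                    config = synthetic_reference_configs()$run,
                    out_dir = tempfile("screen_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_run_config(config, p("run_config.yaml"))
  unlink(p(".failed_stage"))

  sim_dir <- p("sim")
  run_stage("simulate", out_dir, {
    sim <- simulate_screen(sim_config, sim_dir)
    stage_log("simulate", "%d targets, %d proteins, %d terms",
              sim_config$n_targets, sim_config$n_proteins,
              sim_config$n_terms)
  })
  sp <- function(f) file.path(sim_dir, f)

  run_stage("kd-qc", out_dir, {
    ct <- read_tsv(sp("ct_table.tsv"))
    kd <- summarize_knockdown(ct)
    write_tsv(kd, p("kd_efficiency.tsv"))
    stage_log("kd-qc", "%d targets, mean knockdown %.1f%%", nrow(kd),
              mean(kd$efficiency_pct))
  })

  run_stage("phenotypes", out_dir, {
    tab <- read_assay_table(sp("assay_table.csv"))
    eff <- assay_effects(tab, config)
    write_tsv(eff, p("assay_effects.tsv"))
    stage_log("phenotypes", "%d tests, %d hits", nrow(eff), sum(eff$hit))
  })

  run_stage("proteomics-de", out_dir, {
    pm <- read_protein_matrix(sp("protein_matrix.tsv"),
                              sp("protein_metadata.tsv"))
    qc <- qc_filter_samples(pm, config$qc_min_proteins)
    write_tsv(qc$report, p("qc_report.tsv"))
    de <- differential_abundance(qc$matrix, config)
    write_tsv(de, p("de_results.tsv"))
    write_tsv(attr(de, "skipped"), p("de_skipped.tsv"))
    write_tsv(target_self_effect(de), p("target_self_effects.tsv"))
    stage_log("proteomics-de", "%d samples kept (%d excluded), %d DE rows",
              ncol(qc$matrix$intensities), sum(qc$report$excluded), nrow(de))
  })

  run_stage("enrich", out_dir, {
    collection <- read_gmt(sp("gene_sets.gmt"))
    bmap <- read_biodomain_map(sp("biodomain_map.tsv"))
    de <- read_tsv(p("de_results.tsv"))
    combos <- unique(de[, c("target", "cell_line")])
    enr <- lapply(seq_len(nrow(combos)), function(i) {
      ranked <- ranked_from_de(de, combos$target[i], combos$cell_line[i])
      res <- enrich_collection(ranked, collection, bmap, config)
      if (nrow(res) == 0L) return(NULL)
      cbind(target = combos$target[i], cell_line = combos$cell_line[i],
            res, stringsAsFactors = FALSE)
    })
    enr <- do.call(rbind, enr)
    write_tsv(enr, p("enrichment_knockdowns.tsv"))

    orth <- read_tsv(sp("ortholog_map.tsv"))
    dis <- read_tsv(sp("disease_effects.tsv"))
    coll_dis <- map_gene_sets(collection, orth)
    ranked_dis <- ranked_list(dis$effect, dis$gene)
    enr_dis <- enrich_collection(ranked_dis, coll_dis, bmap, config)
    write_tsv(enr_dis, p("enrichment_disease.tsv"))
    stage_log("enrich", "%d knockdown results, %d disease results; %d significant disease terms",
              nrow(enr), nrow(enr_dis),
              sum(enr_dis$p_adj <= config$sig_threshold))
  })

  run_stage("concordance", out_dir, {
    bmap <- read_biodomain_map(sp("biodomain_map.tsv"))
    enr <- read_tsv(p("enrichment_knockdowns.tsv"))
    enr_dis <- read_tsv(p("enrichment_disease.tsv"))
    combos <- unique(enr[, c("target", "cell_line")])
    pairs <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- enr[enr$target == combos$target[i] &
                   enr$cell_line == combos$cell_line[i], , drop = FALSE]
      pt <- suppressWarnings(
        zero_impute_pairs(sub, enr_dis, bmap, config$sig_threshold))
      if (nrow(pt) == 0L) return(NULL)
      cbind(target = combos$target[i], cell_line = combos$cell_line[i],
            pt, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairs)
    write_tsv(pairs, p("term_pairs.tsv"))
    dk <- domain_kendall(pairs, config)
    write_tsv(dk, p("domain_kendall.tsv"))
    write_tsv(quadrant_counts(pairs), p("quadrants.tsv"))

    de <- read_tsv(p("de_results.tsv"))
    dis <- read_tsv(sp("disease_effects.tsv"))
    orth <- read_tsv(sp("ortholog_map.tsv"))
    collection <- read_gmt(sp("gene_sets.gmt"))
    pdom <- protein_biodomains(collection, bmap)
    dp <- domain_protein_pearson(de, dis, orth, pdom, config)
    write_tsv(dp, p("domain_pearson.tsv"))
    stage_log("concordance", "%d domain tests, %d reversals",
              sum(dk$tested), sum(dk$direction == "reversal"))
  })

  run_stage("integrate", out_dir, {
    eff <- read_tsv(p("assay_effects.tsv"))
    enr <- read_tsv(p("enrichment_knockdowns.tsv"))
    ptc <- phenotype_nes_correlation(eff, enr, config)
    write_tsv(ptc, p("phenotype_term_corr.tsv"))
    dk <- read_tsv(p("domain_kendall.tsv"))
    verdicts <- call_top_tier(eff, dk, config)
    write_tsv(verdicts, p("verdicts.tsv"))
    stage_log("integrate", "%d targets, %d top-tier", nrow(verdicts),
              sum(verdicts$top_tier))
  })

  manifest <- run_stage("manifest", out_dir, {
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      c("manifest.json", ".failed_stage")
    ))
    sums <- tools::md5sum(file.path(out_dir, files))
    m <- list(
      seed = config$seed,
      config_hash = unname(tools::md5sum(p("run_config.yaml"))),
      stages = c("simulate", "kd-qc", "phenotypes", "proteomics-de",
                 "enrich", "concordance", "integrate"),
      files = data.frame(path = files, md5 = unname(sums),
                         stringsAsFactors = FALSE),
      created = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(m, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    m
  })
  invisible(manifest)
}
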