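# Synthetic screen generator with planted ground truth.
#
# Emulates the statistical structure the analysis assumes: batch random
# effects on assay readouts (lognormal on the raw scale, normal on log2),
# a sensitized second cell line with amplified planted effects,
# biodomain-coherent proteomic shifts proportional to a latent per-gene
# disease involvement, a disease effect vector built from the same latent
# involvement, and missing-completely-at-random proteomic dropout with a
# few heavily degraded samples for the QC filter to catch.

#' Default assay panel design
#'
#' Four assays mirroring a microglial screening panel: a viability assay
#' (3 batches x 3 replicates), a mitochondrial membrane potential assay
#' (7 x 3), a phagocytosis assay (3 x 4) and an NF-kB reporter assay
#' (3 x 4) run with and without LPS induction.
#'
#' @return data.frame `assay`, `n_batches`, `reps_per_batch`, `dosed`.
#' @export
default_assay_design <- function() {
  data.frame(
    assay = c("alamarblue", "mitotracker", "phagocytosis", "nfkb"),
    n_batches = c(3L, 7L, 3L, 3L),
    reps_per_batch = c(3L, 3L, 4L, 4L),
    dosed = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines the synthetic study: its size, the planted ground truth and
#' every noise parameter. The defaults describe the reference synthetic
#' screen used throughout the package: 12 targets in 2 cell lines across
#' 4 assays, 2,000 proteins, 100 terms over 6 biodomains, and 3 planted
#' dual-evidence targets (assay effect plus domain-coherent proteomic
#' reversal).
#'
#' @param n_targets Number of siRNA targets. Default 12.
#' @param cell_lines Cell line labels; the second is the sensitized
#'   background whose planted effects are amplified.
#' @param sensitization_multiplier Fold amplification of planted effects
#'   in the sensitized line. Default 1.5.
#' @param n_proteins,n_terms,term_size_range Annotation dimensions.
#' @param domains Biodomain vocabulary used by the simulation (must be a
#'   subset of [biodomain_vocabulary()]).
#' @param disease_up_domains,disease_down_domains Domains whose genes are
#'   shifted up / down in the disease effect vector; remaining domains are
#'   centered at zero.
#' @param disease_effect_mean,disease_effect_sd Mean and SD (log2 units)
#'   of the latent per-gene disease involvement within affected domains.
#' @param n_planted_dual Targets planted with both assay effects and
#'   proteomic reversal. Default 3.
#' @param n_planted_assay_only Targets planted with assay effects only.
#' @param n_planted_reversal_only Targets planted with proteomic reversal
#'   only. Default 0.
#' @param domains_per_reversal Biodomains reversed per planted target.
#' @param assays_per_planted Assays carrying the planted effect per
#'   assay-planted target.
#' @param assay_effect_log2 Planted assay effect (log2 fold change) in the
#'   control cell line. Default -1.
#' @param batch_sd SD of the per-batch random intercept (log2 units).
#' @param assay_noise_sd SD of replicate measurement noise (log2 units).
#' @param assay_baseline Raw readout baseline (assay units).
#' @param lps_multiplier Raw-scale induction factor for LPS-dosed wells.
#' @param assay_design Assay panel, see [default_assay_design()].
#' @param reversal_scale Proteomic reversal strength: planted shifts are
#'   `-reversal_scale * involvement` for genes of the planted domains.
#' @param knockdown_lfc Log2 shift of the targeted protein itself.
#' @param knockdown_exempt_targets Targets whose own protein is not
#'   shifted (emulating post-transcriptional escape).
#' @param proteome_baseline_mean,proteome_baseline_sd Per-protein baseline
#'   log2 intensity distribution.
#' @param proteome_residual_sd Replicate noise SD on log2 intensities.
#' @param psen2_proteome_scale Disease-like baseline shift of the
#'   sensitized line's proteome (`scale * involvement`), cancelling in
#'   within-line contrasts.
#' @param replicates_per_group Proteome replicates per siRNA and cell
#'   line. Default 5.
#' @param dropout_rate Missing-completely-at-random dropout probability.
#' @param n_bad_samples,bad_dropout_rate Number of degraded samples and
#'   their elevated dropout rate (exercises the QC filter).
#' @param qpcr_efficiency True knockdown efficiency for qPCR tables.
#' @param qpcr_ct_sd Replicate SD of Ct values (cycles).
#' @param qpcr_replicates qPCR replicates per condition. Default 3.
#' @param seed Integer seed; every generator draws from a substream
#'   derived deterministically from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_targets = 12L,
    cell_lines = c("scramble", "psen2_kd"),
    sensitization_multiplier = 1.5,
    n_proteins = 2000L,
    n_terms = 100L,
    term_size_range = c(10L, 50L),
    domains = c("Immune Response", "Mitochondrial Metabolism",
                "Lipid Metabolism", "Synapse", "Apoptosis",
                "Oxidative Stress"),
    disease_up_domains = c("Immune Response", "Lipid Metabolism",
                           "Oxidative Stress"),
    disease_down_domains = c("Mitochondrial Metabolism", "Synapse"),
    disease_effect_mean = 1,
    disease_effect_sd = 0.3,
    n_planted_dual = 3L,
    n_planted_assay_only = 2L,
    n_planted_reversal_only = 0L,
    domains_per_reversal = 2L,
    assays_per_planted = 2L,
    assay_effect_log2 = -1,
    batch_sd = 0.25,
    assay_noise_sd = 0.15,
    assay_baseline = 1000,
    lps_multiplier = 4,
    assay_design = default_assay_design(),
    reversal_scale = 0.8,
    knockdown_lfc = -1.5,
    knockdown_exempt_targets = character(0),
    proteome_baseline_mean = 25,
    proteome_baseline_sd = 2,
    proteome_residual_sd = 0.3,
    psen2_proteome_scale = 0.5,
    replicates_per_group = 5L,
    dropout_rate = 0.08,
    n_bad_samples = 2L,
    bad_dropout_rate = 0.7,
    qpcr_efficiency = 0.7,
    qpcr_ct_sd = 0.1,
    qpcr_replicates = 3L,
    seed = 1L) {
  cfg <- as.list(environment())
  if (n_targets < 1L || n_proteins < 1L || n_terms < 1L)
    stop("all counts must be at least 1")
  if (any(c(batch_sd, assay_noise_sd, disease_effect_sd,
            proteome_residual_sd, qpcr_ct_sd) < 0))
    stop("standard deviations must be non-negative")
  if (dropout_rate < 0 || dropout_rate >= 1 ||
      bad_dropout_rate < 0 || bad_dropout_rate >= 1)
    stop("dropout rates must lie in [0, 1)")
  if (length(term_size_range) != 2L ||
      term_size_range[1] < 2L || term_size_range[2] < term_size_range[1])
    stop("term_size_range must be an increasing pair with min >= 2")
  unknown <- setdiff(domains, biodomain_vocabulary())
  if (length(unknown) > 0L)
    stop("domains outside the declared vocabulary: ",
         paste(unknown, collapse = ", "))
  if (!all(c(disease_up_domains, disease_down_domains) %in% domains))
    stop("disease-affected domains must be among the simulated domains")
  if (length(intersect(disease_up_domains, disease_down_domains)) > 0L)
    stop("a domain cannot be both disease-up and disease-down")
  n_planted <- n_planted_dual + n_planted_assay_only + n_planted_reversal_only
  if (n_planted > n_targets)
    stop("planted targets exceed n_targets")
  pool_size <- floor(n_proteins / length(domains))
  if (term_size_range[2] > pool_size)
    stop("infeasible term sizes: max term size ", term_size_range[2],
         " exceeds the per-domain gene pool of ", pool_size)
  if (n_planted > 0L && (n_planted_dual + n_planted_reversal_only) >
        pool_size)
    stop("too many reversal targets for the per-domain gene pool")
  if ((n_planted_dual + n_planted_assay_only > 0L) &&
        assays_per_planted > nrow(assay_design))
    stop("assays_per_planted exceeds the assay panel size")
  cfg$n_targets <- as.integer(n_targets)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# deterministic substream seeds per generator
sim_seed <- function(config, stage) {
  offs <- c(annotation = 101L, truth = 211L, proteome = 307L,
            assay = 401L, qpcr = 503L)
  (config$seed * 7L + offs[[stage]]) %% .Machine$integer.max
}

#' Generate the synthetic annotation: gene sets and biodomain map
#'
#' Genes are partitioned into one contiguous pool per domain; each term
#' samples its genes from its domain's pool (genes may recur across terms
#' of a domain), so terms are domain-coherent and each term is annotated
#' to exactly one domain. Terms are allocated to domains as evenly as
#' possible.
#'
#' @param config A [simulation_config()].
#' @return List of class `screen_annotation` with `collection` (a
#'   [gene_set_collection()]), `biodomain_map` (data.frame `term_id`,
#'   `biodomain`) and `gene_domains` (data.frame `gene`, `domain`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(sim_seed(config, "annotation"), {
    genes <- sprintf("G%05d", seq_len(config$n_proteins))
    nd <- length(config$domains)
    pool_id <- rep(seq_len(nd), length.out = config$n_proteins,
                   each = ceiling(config$n_proteins / nd))[
                     seq_len(config$n_proteins)]
    gene_domains <- data.frame(gene = genes,
                               domain = config$domains[pool_id],
                               stringsAsFactors = FALSE)
    pools <- split(genes, gene_domains$domain)[config$domains]
    base <- config$n_terms %/% nd
    extra <- config$n_terms %% nd
    terms_per_domain <- rep(base, nd) + c(rep(1L, extra), rep(0L, nd - extra))
    sizes_lo <- config$term_size_range[1]
    sizes_hi <- config$term_size_range[2]
    sets <- list()
    map <- list()
    idx <- 0L
    for (d in seq_len(nd)) {
      for (j in seq_len(terms_per_domain[d])) {
        idx <- idx + 1L
        id <- sprintf("TERM%04d", idx)
        size <- if (sizes_hi > sizes_lo)
          sample(sizes_lo:sizes_hi, 1L) else sizes_lo
        sets[[id]] <- sample(pools[[d]], size)
        map[[id]] <- data.frame(term_id = id,
                                biodomain = config$domains[d],
                                stringsAsFactors = FALSE)
      }
    }
    structure(
      list(collection = gene_set_collection(sets),
           biodomain_map = do.call(rbind, map),
           gene_domains = gene_domains),
      class = "screen_annotation"
    )
  })
}

#' Build the planted ground truth of a synthetic screen
#'
#' Draws the latent per-gene disease involvement (positive in disease-up
#' domains, negative in disease-down domains, centered at zero elsewhere)
#' and assigns target roles: `dual` (assay effect + proteomic reversal),
#' `assay_only`, `reversal_only`, or `null`. Each reversal-planted target
#' is assigned biodomains cycling through the disease-affected domains,
#' and targets its first planted domain's pool (so its own protein sits in
#' relevant biology); each assay-planted target is assigned a block of
#' assays from the panel. Planted effects are amplified by the
#' sensitization multiplier in the second cell line.
#'
#' @param config A [simulation_config()].
#' @param annotation From [generate_annotation()].
#' @return List of class `synthetic_truth` with `targets`,
#'   `assay_effects`, `gene_involvement` data.frames.
#' @export
make_synthetic_truth <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(annotation, "screen_annotation"))
  with_local_seed(sim_seed(config, "truth"), {
    gd <- annotation$gene_domains
    dirs <- ifelse(gd$domain %in% config$disease_up_domains, 1,
                   ifelse(gd$domain %in% config$disease_down_domains, -1, 0))
    raw <- rnorm(nrow(gd), config$disease_effect_mean,
                 config$disease_effect_sd)
    noise0 <- rnorm(nrow(gd), 0, config$disease_effect_sd)
    involvement <- ifelse(dirs != 0, dirs * raw, noise0)
    gene_involvement <- data.frame(gene = gd$gene, domain = gd$domain,
                                   disease_direction = dirs,
                                   involvement = involvement,
                                   stringsAsFactors = FALSE)

    roles <- c(rep("dual", config$n_planted_dual),
               rep("assay_only", config$n_planted_assay_only),
               rep("reversal_only", config$n_planted_reversal_only))
    roles <- c(roles, rep("null", config$n_targets - length(roles)))

    pools <- split(gd$gene, gd$domain)[config$domains]
    taken <- setNames(rep(0L, length(pools)), names(pools))
    take_gene <- function(dom) {
      taken[dom] <<- taken[dom] + 1L
      pool <- pools[[dom]]
      pool[length(pool) - taken[dom] + 1L]  # allocate from the pool's end
    }

    eligible <- c(config$disease_up_domains, config$disease_down_domains)
    # interleave up/down so a dual target typically reverses one of each
    if (length(config$disease_down_domains) > 0L &&
        length(config$disease_up_domains) > 0L) {
      nu <- length(config$disease_up_domains)
      eligible <- as.vector(rbind(
        config$disease_up_domains[rep(seq_len(nu),
          length.out = max(nu, length(config$disease_down_domains)))],
        config$disease_down_domains[rep(
          seq_along(config$disease_down_domains),
          length.out = max(nu, length(config$disease_down_domains)))]
      ))
      eligible <- unique(eligible)
    }

    assays <- config$assay_design$assay
    rev_i <- 0L
    assay_i <- 0L
    dom_cycle <- 0L
    rows <- lapply(seq_along(roles), function(i) {
      role <- roles[i]
      planted_domains <- character(0)
      planted_assays <- character(0)
      if (role %in% c("dual", "reversal_only")) {
        planted_domains <- eligible[
          ((dom_cycle + seq_len(config$domains_per_reversal) - 1L) %%
             length(eligible)) + 1L]
        dom_cycle <<- dom_cycle + config$domains_per_reversal
        gene <- take_gene(planted_domains[1])
      } else {
        dom <- config$domains[((i - 1L) %% length(config$domains)) + 1L]
        gene <- take_gene(dom)
      }
      if (role %in% c("dual", "assay_only")) {
        planted_assays <- assays[
          ((assay_i + seq_len(config$assays_per_planted) - 1L) %%
             length(assays)) + 1L]
        assay_i <<- assay_i + config$assays_per_planted
      }
      data.frame(target = gene, role = role,
                 planted_domains = paste(planted_domains, collapse = ";"),
                 planted_assays = paste(planted_assays, collapse = ";"),
                 knockdown_efficiency = config$qpcr_efficiency,
                 stringsAsFactors = FALSE)
    })
    targets <- do.call(rbind, rows)

    design <- config$assay_design
    eff_rows <- list()
    for (i in seq_len(nrow(targets))) {
      pa <- strsplit(targets$planted_assays[i], ";", fixed = TRUE)[[1]]
      for (a in seq_len(nrow(design))) {
        doses <- if (design$dosed[a]) c("none", "lps") else "none"
        for (dose in doses) {
          for (cl_i in seq_along(config$cell_lines)) {
            mult <- if (cl_i >= 2L) config$sensitization_multiplier else 1
            eff <- if (design$assay[a] %in% pa)
              config$assay_effect_log2 * mult else 0
            eff_rows[[length(eff_rows) + 1L]] <- data.frame(
              target = targets$target[i], assay = design$assay[a],
              cell_line = config$cell_lines[cl_i], dose = dose,
              effect = eff, stringsAsFactors = FALSE)
          }
        }
      }
    }
    structure(
      list(targets = targets,
           assay_effects = do.call(rbind, eff_rows),
           gene_involvement = gene_involvement),
      class = "synthetic_truth"
    )
  })
}

#' Disease effect table from the planted truth
#'
#' The meta-analysis-style disease effect of each gene is its latent
#' involvement: genes of disease-up domains have positive mean shift,
#' disease-down domains negative, all others are centered at zero (the
#' involvement SD is the noise). Gene ids are translated to the
#' disease-side (human ortholog) identifier space.
#'
#' @param config A [simulation_config()].
#' @param annotation From [generate_annotation()].
#' @param truth From [make_synthetic_truth()].
#' @return data.frame `gene` (disease-side id), `effect`.
#' @export
generate_disease_effects <- function(config, annotation, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.frame(gene = paste0("H", truth$gene_involvement$gene),
             effect = truth$gene_involvement$involvement,
             stringsAsFactors = FALSE)
}

#' Ortholog map between perturbation-side and disease-side gene ids
#'
#' One-to-one by construction; ambiguity handling is exercised by
#' corrupting this map in tests.
#'
#' @param annotation From [generate_annotation()].
#' @return data.frame `protein`, `disease_gene`.
#' @export
generate_ortholog_map <- function(annotation) {
  data.frame(protein = annotation$gene_domains$gene,
             disease_gene = paste0("H", annotation$gene_domains$gene),
             stringsAsFactors = FALSE)
}

#' Generate knockdown proteome matrices with planted reversals
#'
#' For every cell line, each target siRNA group and a control group get
#' `replicates_per_group` samples of log2 intensities: a per-protein
#' baseline, a disease-like baseline shift in the sensitized line, the
#' planted group shifts, and replicate noise. For a reversal-planted
#' target, genes of its planted domains are shifted by
#' `-reversal_scale * involvement` (down where the disease goes up and
#' vice versa), amplified in the sensitized line; the targeted protein
#' itself is shifted by `knockdown_lfc` unless exempt. Dropout is applied
#' missing-completely-at-random, with `n_bad_samples` degraded samples at
#' the elevated rate.
#'
#' @param config A [simulation_config()].
#' @param annotation From [generate_annotation()].
#' @param truth From [make_synthetic_truth()].
#' @return A [protein_matrix()].
#' @export
generate_knockdown_proteomes <- function(config, annotation, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_local_seed(sim_seed(config, "proteome"), {
    genes <- annotation$gene_domains$gene
    n <- length(genes)
    w <- truth$gene_involvement$involvement
    baseline <- rnorm(n, config$proteome_baseline_mean,
                      config$proteome_baseline_sd)
    groups <- c("control", truth$targets$target)
    shifts <- matrix(0, n, length(groups),
                     dimnames = list(genes, groups))
    for (i in seq_len(nrow(truth$targets))) {
      tg <- truth$targets$target[i]
      if (truth$targets$role[i] %in% c("dual", "reversal_only")) {
        doms <- strsplit(truth$targets$planted_domains[i], ";",
                         fixed = TRUE)[[1]]
        in_dom <- annotation$gene_domains$domain %in% doms
        shifts[in_dom, tg] <- -config$reversal_scale * w[in_dom]
      }
      if (!(tg %in% config$knockdown_exempt_targets))
        shifts[tg, tg] <- shifts[tg, tg] + config$knockdown_lfc
    }
    cols <- list()
    meta <- list()
    for (cl_i in seq_along(config$cell_lines)) {
      cl <- config$cell_lines[cl_i]
      cl_shift <- if (cl_i >= 2L) config$psen2_proteome_scale * w else 0
      mult <- if (cl_i >= 2L) config$sensitization_multiplier else 1
      for (g in groups) {
        planted <- shifts[, g] * mult
        for (r in seq_len(config$replicates_per_group)) {
          id <- sprintf("%s.%s.r%d", cl, g, r)
          cols[[id]] <- baseline + cl_shift + planted +
            rnorm(n, 0, config$proteome_residual_sd)
          meta[[id]] <- data.frame(sample = id, target = g, cell_line = cl,
                                   replicate = as.character(r),
                                   stringsAsFactors = FALSE)
        }
      }
    }
    X <- do.call(cbind, cols)
    rownames(X) <- genes
    rate <- rep(config$dropout_rate, ncol(X))
    if (config$n_bad_samples > 0L) {
      bad <- sample(ncol(X), min(config$n_bad_samples, ncol(X)))
      rate[bad] <- config$bad_dropout_rate
    }
    drop_mask <- matrix(runif(length(X)), nrow(X), ncol(X)) <
      rep(rate, each = nrow(X))
    X[drop_mask] <- NA_real_
    protein_matrix(X, do.call(rbind, meta))
  })
}

#' Generate replicate-level assay readout tables
#'
#' Raw readouts follow
#' `baseline * 2^(planted effect + batch intercept + noise)`, i.e.
#' lognormal measurement noise on the raw scale and normal noise on the
#' log2 scale, with batch intercepts drawn per assay, cell line, dose and
#' batch from `Normal(0, batch_sd)`. Control wells are included in every
#' stratum. LPS-dosed wells of dosed assays have an induced baseline.
#'
#' @param config A [simulation_config()].
#' @param truth From [make_synthetic_truth()].
#' @return data.frame `assay`, `target`, `cell_line`, `dose`, `batch`,
#'   `replicate`, `readout`.
#' @export
generate_assay_data <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_local_seed(sim_seed(config, "assay"), {
    design <- config$assay_design
    eff <- truth$assay_effects
    ekey <- paste(eff$target, eff$assay, eff$cell_line, eff$dose, sep = "\r")
    targets <- c("control", truth$targets$target)
    rows <- list()
    for (a in seq_len(nrow(design))) {
      doses <- if (design$dosed[a]) c("none", "lps") else "none"
      for (cl in config$cell_lines) {
        for (dose in doses) {
          base <- config$assay_baseline *
            if (dose == "lps") config$lps_multiplier else 1
          for (b in seq_len(design$n_batches[a])) {
            bint <- rnorm(1, 0, config$batch_sd)
            for (tg in targets) {
              e <- if (tg == "control") 0 else
                eff$effect[match(paste(tg, design$assay[a], cl, dose,
                                       sep = "\r"), ekey)]
              nr <- design$reps_per_batch[a]
              noise <- rnorm(nr, 0, config$assay_noise_sd)
              rows[[length(rows) + 1L]] <- data.frame(
                assay = design$assay[a], target = tg, cell_line = cl,
                dose = dose, batch = sprintf("b%02d", b),
                replicate = as.character(seq_len(nr)),
                readout = base * 2^(e + bint + noise),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate qPCR Ct tables consistent with the planted knockdown
#'
#' Each target gets replicate Ct values for target-siRNA and
#' control-siRNA conditions against a reference gene; the knockdown shifts
#' the target-condition Ct by `-log2(1 - efficiency)` cycles.
#'
#' @param config A [simulation_config()].
#' @param truth From [make_synthetic_truth()].
#' @return data.frame `gene`, `condition`, `replicate`, `ct_gene`,
#'   `ct_ref`.
#' @export
generate_qpcr_data <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_local_seed(sim_seed(config, "qpcr"), {
    rows <- list()
    for (i in seq_len(nrow(truth$targets))) {
      tg <- truth$targets$target[i]
      dct <- -log2(1 - truth$targets$knockdown_efficiency[i])
      for (cond in c("control_sirna", "target_sirna")) {
        shift <- if (cond == "target_sirna") dct else 0
        nr <- config$qpcr_replicates
        rows[[length(rows) + 1L]] <- data.frame(
          gene = tg, condition = cond, replicate = as.character(seq_len(nr)),
          ct_gene = rnorm(nr, 25 + shift, config$qpcr_ct_sd),
          ct_ref = rnorm(nr, 20, config$qpcr_ct_sd),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic screen
#'
#' Runs every generator from one configuration and optionally writes all
#' inputs (and the ground truth) in the exact formats the pipeline reads.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; created if needed.
#' @return List with `annotation`, `truth`, `disease_effects`,
#'   `ortholog_map`, `proteome`, `assay_table`, `ct_table` and, when
#'   written, `files` (named vector of paths).
#' @export
simulate_screen <- function(config = simulation_config(), out_dir = NULL) {
  annotation <- generate_annotation(config)
  truth <- make_synthetic_truth(config, annotation)
  out <- list(
    annotation = annotation,
    truth = truth,
    disease_effects = generate_disease_effects(config, annotation, truth),
    ortholog_map = generate_ortholog_map(annotation),
    proteome = generate_knockdown_proteomes(config, annotation, truth),
    assay_table = generate_assay_data(config, truth),
    ct_table = generate_qpcr_data(config, truth)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    files <- c(
      gene_sets = p("gene_sets.gmt"),
      biodomain_map = p("biodomain_map.tsv"),
      protein_matrix = p("protein_matrix.tsv"),
      protein_metadata = p("protein_metadata.tsv"),
      assay_table = p("assay_table.csv"),
      ct_table = p("ct_table.tsv"),
      disease_effects = p("disease_effects.tsv"),
      ortholog_map = p("ortholog_map.tsv"),
      truth_targets = p("truth_targets.tsv"),
      truth_assay_effects = p("truth_assay_effects.tsv"),
      truth_gene_involvement = p("truth_gene_involvement.tsv")
    )
    write_gmt(annotation$collection, files["gene_sets"])
    write_biodomain_map(annotation$biodomain_map, files["biodomain_map"])
    write_protein_matrix(out$proteome, files["protein_matrix"],
                         files["protein_metadata"])
    write_assay_table(out$assay_table, files["assay_table"])
    write_tsv(out$ct_table, files["ct_table"])
    write_tsv(out$disease_effects, files["disease_effects"])
    write_tsv(out$ortholog_map, files["ortholog_map"])
    write_tsv(truth$targets, files["truth_targets"])
    write_tsv(truth$assay_effects, files["truth_assay_effects"])
    write_tsv(truth$gene_involvement, files["truth_gene_involvement"])
    out$files <- files
  }
  out
}
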