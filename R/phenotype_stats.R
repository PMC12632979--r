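#' Per-batch log2 fold changes from replicate assay readouts
#'
#' Replicates are first averaged within each batch, then a log2 fold change
#' is computed comparing the average target-siRNA readout to the average
#' control-siRNA readout within the same assay, cell line, LPS dose and
#' batch. Cell lines (and doses) are never mixed.
#'
#' @param table Assay table: data.frame with columns `assay`, `target`,
#'   `cell_line`, `dose`, `batch`, `replicate`, `readout` (raw assay units,
#'   positive). Control wells carry `target == control`.
#' @param control Label of the control siRNA. Default `"control"`.
#' @return data.frame with one row per assay x target x cell line x dose x
#'   batch: columns `assay`, `target`, `cell_line`, `dose`, `batch`,
#'   `log2fc`.
#' @export
batch_log2fc <- function(table, control = "control") {
  need <- c("assay", "target", "cell_line", "dose", "batch", "replicate", "readout")
  if (!all(need %in% names(table)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$readout)))
    stop("readouts must be finite")
  strata <- interaction(table$assay, table$cell_line, table$dose, table$batch,
                        drop = TRUE, lex.order = TRUE)
  out <- lapply(split(table, strata), function(s) {
    key <- sprintf("assay=%s cell_line=%s dose=%s batch=%s",
                   s$assay[1], s$cell_line[1], s$dose[1], s$batch[1])
    ctrl <- s$readout[s$target == control]
    if (length(ctrl) == 0L)
      stop("stratum lacks control replicates: ", key)
    mc <- mean(ctrl)
    if (mc <= 0) stop("nonpositive control mean in stratum: ", key)
    tg <- s[s$target != control, , drop = FALSE]
    if (nrow(tg) == 0L) return(NULL)
    mt <- tapply(tg$readout, tg$target, mean)
    if (any(mt <= 0))
      stop("nonpositive target mean in stratum: ", key, " (",
           paste(names(mt)[mt <= 0], collapse = ", "), ")")
    data.frame(assay = s$assay[1], target = names(mt),
               cell_line = s$cell_line[1], dose = s$dose[1],
               batch = s$batch[1], log2fc = log2(unname(mt) / mc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$assay, out$cell_line, out$dose, out$target, out$batch), ,
      drop = FALSE]
}

#' Fit a random-intercept mixed model to per-batch log2 fold changes
#'
#' Models log2 fold change as a cell-means fixed effect per target with a
#' random intercept per experimental batch:
#' `log2fc ~ 0 + target + (1 | batch)`, fitted by REML with [lme4::lmer()].
#' The records must come from a single assay x cell line x dose stratum;
#' cell lines are analyzed separately throughout.
#'
#' With fewer than two batches the random effect is unidentifiable and the
#' fit downgrades to ordinary least squares with a message. The batch
#' variance estimate is non-negative by construction (boundary REML).
#'
#' @param records Output rows of [batch_log2fc()] for one stratum.
#' @param ref_dist `"z"` for normal-reference tests of the fixed effects,
#'   or `"satterthwaite"` for t-tests with Satterthwaite degrees of freedom
#'   (requires the lmerTest package).
#' @return Object of class `assay_lmm`: list with elements `fit`, `method`
#'   (`"reml"` or `"ols"`), `batch_sd`, `resid_sd`, `n_batches`, `ref_dist`
#'   and the stratum labels.
#' @export
fit_random_intercept_lmm <- function(records, ref_dist = c("z", "satterthwaite")) {
  ref_dist <- match.arg(ref_dist)
  stopifnot(all(c("target", "batch", "log2fc") %in% names(records)))
  if (length(unique(records$assay)) > 1L ||
      length(unique(records$cell_line)) > 1L ||
      length(unique(records$dose)) > 1L)
    stop("records must come from a single assay x cell line x dose stratum")
  records$target <- factor(records$target)
  records$batch <- factor(records$batch)
  n_batches <- nlevels(records$batch)
  if (n_batches >= 2L) {
    if (ref_dist == "satterthwaite") {
      if (!requireNamespace("lmerTest", quietly = TRUE))
        stop("ref_dist = 'satterthwaite' requires the lmerTest package")
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(log2fc ~ 0 + target + (1 | batch), data = records,
                       REML = TRUE)
      ))
    } else {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(log2fc ~ 0 + target + (1 | batch), data = records,
                   REML = TRUE)
      ))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    batch_sd <- vc$sdcor[vc$grp == "batch"]
    resid_sd <- vc$sdcor[vc$grp == "Residual"]
    method <- "reml"
  } else {
    message("fewer than 2 batches; downgrading to a fixed-effects-only fit")
    fit <- lm(log2fc ~ 0 + target, data = records)
    batch_sd <- 0
    resid_sd <- summary(fit)$sigma
    method <- "ols"
  }
  structure(
    list(fit = fit, method = method, batch_sd = batch_sd,
         resid_sd = resid_sd, n_batches = n_batches, ref_dist = ref_dist,
         assay = records$assay[1], cell_line = records$cell_line[1],
         dose = records$dose[1], targets = levels(records$target)),
    class = "assay_lmm"
  )
}

#' @export
print.assay_lmm <- function(x, ...) {
  cat(sprintf(
    "assay_lmm [%s]: %s / %s / dose %s; %d targets, %d batches; batch SD %.3f, residual SD %.3f\n",
    x$method, x$assay, x$cell_line, x$dose, length(x$targets), x$n_batches,
    x$batch_sd, x$resid_sd
  ))
  invisible(x)
}

#' Marginal-mean tests of per-target knockdown effects
#'
#' In the cell-means parameterization each fixed-effect coefficient is the
#' estimated marginal mean log2 fold change for one target. Each is tested
#' against zero, two-sided, using the model's reference distribution
#' (normal by default, Satterthwaite t if the model was fitted that way).
#'
#' @param model An `assay_lmm` from [fit_random_intercept_lmm()].
#' @return data.frame with columns `assay`, `target`, `cell_line`, `dose`,
#'   `estimate`, `se`, `p`, `n_batches`, `batch_sd`, `resid_sd`.
#' @export
marginal_mean_tests <- function(model) {
  stopifnot(inherits(model, "assay_lmm"))
  if (model$method == "reml") {
    beta <- lme4::fixef(model$fit)
    se <- sqrt(diag(as.matrix(vcov(model$fit))))
  } else {
    cf <- summary(model$fit)$coefficients
    beta <- cf[, "Estimate"]
    se <- cf[, "Std. Error"]
  }
  est <- unname(beta)
  se <- unname(se)
  if (model$ref_dist == "satterthwaite" && model$method == "reml") {
    cf <- summary(model$fit)$coefficients
    p <- unname(cf[, "Pr(>|t|)"])
  } else {
    z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(
    assay = model$assay, target = sub("^target", "", names(beta)),
    cell_line = model$cell_line, dose = model$dose,
    estimate = est, se = se, p = p, n_batches = model$n_batches,
    batch_sd = model$batch_sd, resid_sd = model$resid_sd,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the standard step-up FDR procedure
#' (`p.adjust(method = "BH")`): adjusted values are order-preserving, at
#' least the raw p, and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  p.adjust(p, method = "BH")
}

#' Flag assay hits by adjusted significance
#'
#' Applies BH correction within the declared family and flags hits at
#' `p_adj <= threshold` (boundary values count as hits).
#'
#' @param effects Output of [marginal_mean_tests()] (rows may span strata).
#' @param threshold Adjusted-p cutoff. Default 0.05.
#' @param family `"assay"`: correct across targets within each
#'   assay x cell line x dose combination (default); `"global"`: one family
#'   for all rows.
#' @return `effects` with added columns `p_adj` and `hit`.
#' @export
call_hits <- function(effects, threshold = 0.05, family = c("assay", "global")) {
  family <- match.arg(family)
  if (nrow(effects) == 0L) {
    effects$p_adj <- numeric(0)
    effects$hit <- logical(0)
    return(effects)
  }
  if (family == "global") {
    effects$p_adj <- bh_adjust(effects$p)
  } else {
    grp <- interaction(effects$assay, effects$cell_line, effects$dose,
                       drop = TRUE)
    effects$p_adj <- NA_real_
    for (g in levels(grp)) {
      idx <- grp == g
      effects$p_adj[idx] <- bh_adjust(effects$p[idx])
    }
  }
  effects$hit <- effects$p_adj <= threshold
  effects
}

#' Full phenotype hit-calling chain
#'
#' Batch averaging, log2 fold change, random-intercept mixed model per
#' assay x cell line x dose stratum, marginal-mean tests and BH-corrected
#' hit calling.
#'
#' @param table Replicate-level assay table (see [batch_log2fc()]).
#' @param config A [run_config()].
#' @param control Control siRNA label.
#' @return data.frame of per-target effects with `p_adj` and `hit` flags.
#' @export
assay_effects <- function(table, config = run_config(), control = "control") {
  lfc <- batch_log2fc(table, control = control)
  strata <- interaction(lfc$assay, lfc$cell_line, lfc$dose, drop = TRUE,
                        lex.order = TRUE)
  res <- lapply(split(lfc, strata), function(s) {
    marginal_mean_tests(fit_random_intercept_lmm(s, ref_dist = config$ref_dist))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  call_hits(res, threshold = config$sig_threshold, family = config$bh_family)
}
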