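#' Biological domain vocabulary
#'
#' The fixed vocabulary of disease-relevant biological domains ("biodomains")
#' used to group Gene Ontology terms. Each domain is a curated set of GO
#' terms; grouping enrichment results by domain is what allows
#' domain-level concordance and reversal scoring.
#'
#' @return Character vector of the 19 canonical biodomain names.
#' @export
biodomain_vocabulary <- function() {
  c(
    "APP Metabolism", "Apoptosis", "Autophagy", "Cell Cycle", "DNA Repair",
    "Endolysosome", "Epigenetic", "Immune Response", "Lipid Metabolism",
    "Metal Binding and Homeostasis", "Mitochondrial Metabolism",
    "Myelination", "Oxidative Stress", "Proteostasis", "RNA Spliceosome",
    "Structural Stabilization", "Synapse", "Tau Homeostasis", "Vasculature"
  )
}

#' Construct a gene-set collection
#'
#' @param sets Named list; each element a character vector of gene ids.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L) stop("collection must contain at least one set")
  ids <- names(sets)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every gene set must be named")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate set id(s): ", paste(dup, collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  if (any(vapply(sets, anyDuplicated, 0L) > 0L))
    stop("genes within a set must be unique")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(ids)), ids)
  structure(
    list(sets = sets, descriptions = descriptions[ids]),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf(
    "gene_set_collection: %d sets, sizes %d-%d (median %g)\n",
    length(x$sets), min(sz), max(sz), median(sz)
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated, fields
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are removed with a warning; duplicate set ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("GMT parse error: line %d has fewer than 3 tab-separated fields", bad[1]))
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, function(g) length(g) - length(unique(g)), 0L)
  if (any(ndup > 0L)) {
    warning(sprintf(
      "removed %d duplicate gene entr%s within %d set(s): %s",
      sum(ndup), if (sum(ndup) == 1L) "y" else "ies", sum(ndup > 0L),
      paste(head(ids[ndup > 0L], 5L), collapse = ", ")
    ))
    sets <- lapply(sets, unique)
  }
  names(sets) <- ids
  gene_set_collection(sets, setNames(desc, ids))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GO-term to biodomain mapping table
#'
#' Tab-separated with columns `term_id` and `biodomain`. A term may map to
#' several domains (one row per pairing). Domain names must come from the
#' declared vocabulary.
#'
#' @param path Path to a TSV file.
#' @param vocabulary Permitted domain names; `NULL` disables the check.
#' @return A data.frame with columns `term_id`, `biodomain` (one row per
#'   term-domain pairing, deduplicated).
#' @export
read_biodomain_map <- function(path, vocabulary = biodomain_vocabulary()) {
  if (!file.exists(path)) stop("biodomain map not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    return(data.frame(term_id = character(), biodomain = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", colClasses = "character")
  need <- c("term_id", "biodomain")
  if (!all(need %in% names(df)))
    stop("biodomain map must have columns: ", paste(need, collapse = ", "))
  df <- unique(df[, need])
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(df$biodomain), vocabulary)
    if (length(unknown) > 0L)
      stop("unknown biodomain name(s): ", paste(unknown, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a biodomain mapping table
#' @param map data.frame with `term_id`, `biodomain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biodomain_map <- function(map, path) {
  write_tsv(map[, c("term_id", "biodomain")], path)
}

#' Construct a protein abundance matrix with sample metadata
#'
#' @param intensities Numeric matrix of log2 intensities, proteins in rows,
#'   samples in columns; `NA` marks a missing (not detected) measurement.
#' @param metadata data.frame with at least columns `sample`, `target`,
#'   `cell_line`, `replicate` covering every column of `intensities`.
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(intensities, metadata) {
  stopifnot(is.matrix(intensities))
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensity matrix must have protein row names and sample column names")
  need <- c("sample", "target", "cell_line", "replicate")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  missing_meta <- setdiff(colnames(intensities), metadata$sample)
  if (length(missing_meta) > 0L)
    stop("sample(s) missing from metadata: ", paste(missing_meta, collapse = ", "))
  metadata <- metadata[match(colnames(intensities), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  if (any(!is.finite(intensities) & !is.na(intensities)))
    stop("intensities must be finite where present")
  structure(list(intensities = intensities, metadata = metadata),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf(
    "protein_matrix: %d proteins x %d samples (%.1f%% missing), %d cell line(s)\n",
    nrow(x$intensities), ncol(x$intensities),
    100 * mean(is.na(x$intensities)),
    length(unique(x$metadata$cell_line))
  ))
  invisible(x)
}

#' Read a protein intensity matrix and its sample metadata
#'
#' The matrix is TSV with the protein id in the first column (`protein`)
#' and one column per sample; empty cells or the literal `NA` are missing
#' values. Metadata is TSV with columns `sample`, `target`, `cell_line`,
#' `replicate`.
#'
#' @param path Matrix TSV path.
#' @param metadata_path Metadata TSV path.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, metadata_path) {
  if (!file.exists(path)) stop("protein matrix not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", check.names = FALSE, na.strings = c("NA", ""))
  if (names(df)[1] != "protein") stop("first matrix column must be 'protein'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("matrix cells must be numeric or missing")
  rownames(mat) <- df$protein
  meta <- read.delim(metadata_path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE, colClasses = "character")
  protein_matrix(mat, meta)
}

#' Write a protein matrix and metadata
#'
#' Missing intensities are written as empty cells.
#'
#' @param pm A [protein_matrix()].
#' @param path Matrix TSV path.
#' @param metadata_path Metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_protein_matrix <- function(pm, path, metadata_path) {
  stopifnot(inherits(pm, "protein_matrix"))
  df <- data.frame(protein = rownames(pm$intensities),
                   pm$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  write_tsv(pm$metadata, metadata_path)
  invisible(path)
}

#' Read a replicate-level assay table
#'
#' CSV with columns `assay`, `target`, `cell_line`, `dose`, `batch`,
#' `replicate`, `readout`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("assay table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(readout = "numeric"))
  need <- c("assay", "target", "cell_line", "dose", "batch", "replicate",
            "readout")
  if (!all(need %in% names(df)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  for (col in setdiff(need, "readout")) df[[col]] <- as.character(df[[col]])
  df
}

#' Write a replicate-level assay table as CSV
#' @param table Assay table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Translate a gene-set collection into another identifier space
#'
#' Maps every gene through a two-column table; genes without a mapping,
#' or with an ambiguous (one-to-many) mapping, are dropped. Sets left
#' empty are removed.
#'
#' @param collection A [gene_set_collection()].
#' @param map data.frame with the source ids in `from` and translated ids
#'   in `to`.
#' @param from,to Column names in `map`.
#' @return A translated [gene_set_collection()].
#' @export
map_gene_sets <- function(collection, map, from = "protein",
                          to = "disease_gene") {
  stopifnot(inherits(collection, "gene_set_collection"))
  amb <- names(which(table(map[[from]]) > 1L))
  map <- map[!(map[[from]] %in% amb), , drop = FALSE]
  lut <- setNames(map[[to]], map[[from]])
  sets <- lapply(collection$sets, function(g) {
    out <- unname(lut[g])
    unique(out[!is.na(out)])
  })
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("no gene set survived identifier mapping")
  gene_set_collection(sets, collection$descriptions[names(sets)])
}

# internal: TSV writer with stable conventions (tab sep, no quoting, NA as NA)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE, ...)
}

#' Pipeline run configuration
#'
#' Collects every analysis threshold in one declarative object. Defaults
#' are the values used throughout the screening analysis.
#'
#' @param sig_threshold Adjusted-p significance cutoff used for hit calling,
#'   enrichment significance and concordance labelling. Default 0.05.
#' @param n_perm Gene-label permutations for enrichment p-values (>= 99).
#' @param min_set_size,max_set_size Gene-set size filters after intersecting
#'   with the ranked list.
#' @param qc_min_proteins Minimum detected proteins per sample; samples with
#'   fewer are excluded (strictly fewer-than). Default 6100.
#' @param min_obs_per_group Minimum non-missing observations per siRNA group
#'   for a protein to enter the ANOVA. Default 3.
#' @param min_terms_per_domain Minimum paired terms for a domain-level rank
#'   correlation. Default 5.
#' @param min_proteins_per_domain Minimum orthologous proteins for a
#'   domain-level Pearson correlation. Default 10.
#' @param min_obs_correlation Minimum knockdown-by-cell-line points for a
#'   phenotype/term correlation. Default 10.
#' @param gsea_weight Weight exponent of the running-sum statistic
#'   (0 = unweighted Kolmogorov-Smirnov, 1 = classic weighted). Default 1.
#' @param ref_dist Reference distribution for mixed-model marginal-mean
#'   tests: `"z"` (normal) or `"satterthwaite"` (t with Satterthwaite
#'   degrees of freedom, via lmerTest).
#' @param bh_family Family scope for BH correction of assay tests: `"assay"`
#'   (all targets within one assay x cell line x dose, the default) or
#'   `"global"` (all tests in the run).
#' @param top_tier_min_hits Minimum assay hits (any assay/cell line) for the
#'   top-tier rule. Default 1.
#' @param top_tier_min_reversals Minimum significant reversal domains for
#'   the top-tier rule. Default 1.
#' @param top_tier_require_reversal If `TRUE` (default) the proteomic
#'   evidence must be a *reversal* (negative correlation with disease);
#'   `FALSE` accepts any significant domain correlation.
#' @param seed Base random seed for permutation procedures.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(sig_threshold = 0.05,
                       n_perm = 10000L,
                       min_set_size = 10L,
                       max_set_size = 500L,
                       qc_min_proteins = 6100L,
                       min_obs_per_group = 3L,
                       min_terms_per_domain = 5L,
                       min_proteins_per_domain = 10L,
                       min_obs_correlation = 10L,
                       gsea_weight = 1,
                       ref_dist = c("z", "satterthwaite"),
                       bh_family = c("assay", "global"),
                       top_tier_min_hits = 1L,
                       top_tier_min_reversals = 1L,
                       top_tier_require_reversal = TRUE,
                       seed = 1L) {
  ref_dist <- match.arg(ref_dist)
  bh_family <- match.arg(bh_family)
  if (!is.numeric(sig_threshold) || sig_threshold <= 0 || sig_threshold >= 1)
    stop("sig_threshold must lie in (0, 1)")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (min_set_size < 2L) stop("min_set_size must be at least 2")
  if (max_set_size < min_set_size) stop("max_set_size < min_set_size")
  if (qc_min_proteins < 0L) stop("qc_min_proteins must be non-negative")
  cfg <- list(
    sig_threshold = sig_threshold, n_perm = as.integer(n_perm),
    min_set_size = as.integer(min_set_size),
    max_set_size = as.integer(max_set_size),
    qc_min_proteins = as.integer(qc_min_proteins),
    min_obs_per_group = as.integer(min_obs_per_group),
    min_terms_per_domain = as.integer(min_terms_per_domain),
    min_proteins_per_domain = as.integer(min_proteins_per_domain),
    min_obs_correlation = as.integer(min_obs_correlation),
    gsea_weight = gsea_weight, ref_dist = ref_dist, bh_family = bh_family,
    top_tier_min_hits = as.integer(top_tier_min_hits),
    top_tier_min_reversals = as.integer(top_tier_min_reversals),
    top_tier_require_reversal = isTRUE(top_tier_require_reversal),
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unspecified fields fall back to the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
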