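## Data ingestion, gene pre-filtering, and report serialization.

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load a feature matrix and labels from delimited files
#'
#' The matrix file has a header row of feature names and one row per
#' sample, with the sample identifier in the first column.  The labels file
#' has columns `(id, label)`; rows are aligned to the matrix by identifier,
#' so the two files may list samples in different orders.  Labels may be
#' coded 0/1 or as two string levels, which are mapped to 0/1 in sorted
#' order (the alphabetically first level becomes 0).
#'
#' @param matrix_path path to the CSV/TSV feature matrix.
#' @param labels_path path to the CSV/TSV labels table.
#' @param covariate_columns optional character vector of matrix columns to
#'   flag as unpenalized covariates (recorded in the `covariates`
#'   attribute as feature indices).
#' @return A [robit_dataset()]; the label coding used is recorded in the
#'   `label_levels` attribute.
#' @export
load_dataset <- function(matrix_path, labels_path, covariate_columns = NULL) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  mat <- read_table_auto(matrix_path)
  lab <- read_table_auto(labels_path)
  if (ncol(lab) < 2) stop("labels file must have (id, label) columns")
  ids <- as.character(mat[[1]])
  x <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(x)) stop("feature matrix contains non-numeric values")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("missing values in feature matrix at (row, column): ",
         paste(sprintf("(%s, %s)", ids[bad[, 1]],
                       colnames(x)[bad[, 2]]), collapse = ", "))
  }
  lab_ids <- as.character(lab[[1]])
  if (!setequal(ids, lab_ids) || anyDuplicated(ids) || anyDuplicated(lab_ids))
    stop("sample IDs of the matrix and labels files do not match 1:1")
  lab <- lab[match(ids, lab_ids), ]
  raw <- lab[[2]]
  levels <- sort(unique(as.character(raw)))
  if (all(as.character(raw) %in% c("0", "1"))) {
    y <- as.integer(as.character(raw))
    levels <- c("0", "1")
  } else {
    if (length(levels) != 2) stop("labels must have exactly two levels")
    y <- as.integer(as.character(raw) == levels[2])
  }
  ds <- robit_dataset(x, y)
  attr(ds, "label_levels") <- levels
  if (!is.null(covariate_columns)) {
    idx <- match(covariate_columns, ds$feature_names)
    if (anyNA(idx)) stop("unknown covariate column(s): ",
                         paste(covariate_columns[is.na(idx)], collapse = ", "))
    attr(ds, "covariates") <- idx
  }
  ds
}

#' Pre-filter genes by coefficient of variation or mean expression
#'
#' Keeps gene `j` when its coefficient of variation (`sd / mean`) is at
#' least `cv_min` *or* its mean is at least `mean_min`.  Intended for
#' log2-normalized expression matrices (samples x genes): the mean
#' criterion then reads as mean log2 expression.  The CV is computed on the
#' values as provided unless `exponentiate = TRUE`, which applies `2^x`
#' first (for when the CV should be taken on the unlogged scale).  Genes
#' with zero mean have an undefined CV and are judged by the mean criterion
#' alone.
#'
#' @param mat numeric matrix, samples in rows, genes in columns.
#' @param cv_min CV threshold (default 5).
#' @param mean_min mean threshold (default 3).
#' @param exponentiate unlog (base 2) before computing the CV.
#' @return List with `matrix` (kept columns), `kept` (indices) and
#'   `names`.
#' @export
filter_genes <- function(mat, cv_min = 5, mean_min = 3,
                         exponentiate = FALSE) {
  mat <- as.matrix(mat)
  vals <- if (exponentiate) 2^mat else mat
  mu_cv <- colMeans(vals)
  sds <- apply(vals, 2, sd)
  cv <- ifelse(mu_cv == 0, NA_real_, sds / mu_cv)
  mu <- colMeans(mat)
  keep <- (!is.na(cv) & cv >= cv_min) | mu >= mean_min
  kept <- unname(which(keep))
  list(matrix = mat[, kept, drop = FALSE], kept = kept,
       names = colnames(mat)[kept])
}

#' Write the subset report, metrics and configuration to an output directory
#'
#' Writes `subsets.json` (the full report), `subsets.csv` (one row per
#' subset: members by name, frequency, then ER / AMLP / AUROC / AUPRC),
#' `diagnostics.json` (chain summary) and `config.json` (the resolved
#' configuration and seed, for reproducibility).
#'
#' @param report a [enumerate_subsets()] report.
#' @param metrics list of [metric_set] objects (or `NULL`), one per subset.
#' @param chain_summary named list of chain diagnostics (or `NULL`).
#' @param outdir output directory (created if missing).
#' @param config named list with the resolved run configuration (or
#'   `NULL`).
#' @return Invisibly, the paths written.
#' @export
save_report <- function(report, metrics = NULL, chain_summary = NULL,
                        outdir, config = NULL) {
  stopifnot(inherits(report, "subset_report"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  member_names <- function(s) {
    if (is.null(report$feature_names)) as.character(s)
    else report$feature_names[s]
  }
  get_metric <- function(field) {
    if (is.null(metrics)) rep(NA_real_, length(report$subsets))
    else vapply(metrics, function(m) as.numeric(m[[field]]), numeric(1))
  }
  tab <- data.frame(
    subset = vapply(report$subsets, function(s)
      paste(member_names(s), collapse = ";"), ""),
    size = lengths(report$subsets),
    frequency = report$frequency,
    er = get_metric("error_rate"),
    amlp = get_metric("amlp"),
    auroc = get_metric("auroc"),
    auprc = get_metric("auprc"))
  csv_path <- file.path(outdir, "subsets.csv")
  write.csv(tab, csv_path, row.names = FALSE)

  json_obj <- list(
    total_draws = report$R,
    unassigned = report$unassigned,
    discarded_features = as.list(member_names(report$discarded)),
    subsets = lapply(seq_along(report$subsets), function(i) {
      entry <- list(members = as.list(member_names(report$subsets[[i]])),
                    member_indices = as.list(report$subsets[[i]]),
                    frequency = report$frequency[i])
      if (!is.null(metrics))
        entry$metrics <- list(er = metrics[[i]]$error_rate,
                              amlp = metrics[[i]]$amlp,
                              auroc = metrics[[i]]$auroc,
                              auprc = metrics[[i]]$auprc)
      entry
    }))
  json_path <- file.path(outdir, "subsets.json")
  jsonlite::write_json(json_obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  paths <- c(csv_path, json_path)
  if (!is.null(chain_summary)) {
    diag_path <- file.path(outdir, "diagnostics.json")
    jsonlite::write_json(chain_summary, diag_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, diag_path)
  }
  if (!is.null(config)) {
    cfg_path <- file.path(outdir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, cfg_path)
  }
  invisible(paths)
}

#' Read back a subset report written by [save_report()]
#'
#' @param path path to a `subsets.json` file.
#' @return A `subset_report` (metrics, if present, in the
#'   `"metrics"` attribute).
#' @export
load_report <- function(path) {
  obj <- jsonlite::read_json(path)
  subsets <- lapply(obj$subsets, function(s)
    as.integer(unlist(s$member_indices)))
  freq <- vapply(obj$subsets, function(s) as.numeric(s$frequency),
                 numeric(1))
  rep_out <- structure(list(subsets = subsets, frequency = freq,
                            R = obj$total_draws,
                            discarded = integer(0),
                            unassigned = obj$unassigned,
                            feature_names = NULL),
                       class = "subset_report")
  if (length(obj$subsets) && !is.null(obj$subsets[[1]]$metrics))
    attr(rep_out, "metrics") <- lapply(obj$subsets, function(s) s$metrics)
  rep_out
}
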