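## Subdivision of MCMC coefficient draws into posterior-mode-like feature
## subsets: per-draw relative-magnitude indicators, low-frequency filtering,
## unique-column enumeration, and top/optimal ranking.

#' Per-draw feature selection indicators
#'
#' For each retained draw, a feature is marked selected when its absolute
#' coefficient exceeds `rel_threshold` times the largest absolute
#' coefficient in that draw.  A draw whose largest coefficient is zero
#' yields an all-zero column.  The intercept must not be included in
#' `beta_draws`.
#'
#' @param beta_draws R x p matrix of coefficient draws (rows = draws,
#'   intercept excluded).
#' @param rel_threshold fraction of the per-draw maximum (default 0.1).
#' @return An object of class `indicator_matrix`: logical `I` (p x R),
#'   per-feature frequencies `f` (row means of `I`), `rel_threshold`,
#'   total draws `R`, `discarded` (empty here; filled by
#'   [filter_low_frequency()]), and `feature_names`.
#' @export
indicator_matrix <- function(beta_draws, rel_threshold = 0.1) {
  beta_draws <- as.matrix(beta_draws)
  if (nrow(beta_draws) < 1L) stop("need at least one draw")
  a <- abs(t(beta_draws))                       # p x R
  mx <- apply(a, 2, max)
  I <- sweep(a, 2, rel_threshold * mx, ">")
  I[, mx == 0] <- FALSE
  structure(list(I = I, f = rowMeans(I), rel_threshold = rel_threshold,
                 R = ncol(I), discarded = integer(0),
                 feature_names = colnames(beta_draws)),
            class = "indicator_matrix")
}

#' Zero out features selected too rarely
#'
#' Features whose selection frequency across draws falls below `min_freq`
#' are treated as jitter introduced by MCMC randomness: their indicator
#' rows are zeroed for all draws and recorded in `discarded`.  Frequencies
#' are recomputed afterwards.
#'
#' @param ind an [indicator_matrix()].
#' @param min_freq minimum selection frequency in \[0, 1\] (default 0.05).
#' @return The filtered `indicator_matrix`.
#' @export
filter_low_frequency <- function(ind, min_freq = 0.05) {
  stopifnot(inherits(ind, "indicator_matrix"),
            min_freq >= 0, min_freq <= 1)
  drop_rows <- which(ind$f < min_freq)
  ind$I[drop_rows, ] <- FALSE
  ind$discarded <- sort(union(ind$discarded, drop_rows))
  ind$f <- rowMeans(ind$I)
  ind
}

#' Enumerate the distinct feature subsets among draws
#'
#' Each distinct indicator column is one feature subset; its frequency is
#' the fraction of all draws showing that column.  All-zero columns are
#' dropped (their share is reported as `unassigned`), so frequencies sum to
#' at most 1.  Subsets are ordered by decreasing frequency, ties broken by
#' lexicographic feature order.
#'
#' @param ind an [indicator_matrix()] (normally after
#'   [filter_low_frequency()]).
#' @return An object of class `subset_report`: `subsets` (list of sorted
#'   integer feature-index vectors), `frequency`, `R`, `discarded`,
#'   `unassigned` (fraction of all-zero draws) and `feature_names`.
#' @export
enumerate_subsets <- function(ind) {
  stopifnot(inherits(ind, "indicator_matrix"))
  keys <- apply(ind$I, 2, function(col) paste(which(col), collapse = ","))
  tab <- table(keys)
  empty <- names(tab) == ""
  unassigned <- if (any(empty)) as.numeric(tab[empty]) / ind$R else 0
  tab <- tab[!empty]
  subsets <- lapply(names(tab), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  freq <- as.numeric(tab) / ind$R
  ord <- order(-freq, vapply(subsets, subset_lex_key, ""))
  structure(list(subsets = subsets[ord], frequency = freq[ord],
                 R = ind$R, discarded = ind$discarded,
                 unassigned = unassigned,
                 feature_names = ind$feature_names),
            class = "subset_report")
}

## fixed-width key so lexicographic feature order sorts correctly as a string
subset_lex_key <- function(s) paste(sprintf("%09d", s), collapse = ",")

#' @export
print.subset_report <- function(x, ...) {
  cat(sprintf("subset_report: %d subsets over %d draws (unassigned %.3f)\n",
              length(x$subsets), x$R, x$unassigned))
  n_show <- min(10L, length(x$subsets))
  for (i in seq_len(n_show)) {
    members <- if (is.null(x$feature_names)) {
      paste(x$subsets[[i]], collapse = ",")
    } else paste(x$feature_names[x$subsets[[i]]], collapse = ",")
    cat(sprintf("  %2d. {%s}  freq %.3f\n", i, members, x$frequency[i]))
  }
  invisible(x)
}

#' Identify the top and the optimal feature subset
#'
#' The *top* subset has the highest posterior frequency (ties: smaller
#' subset, then lexicographic order); the *optimal* subset has the smallest
#' cross-validated AMLP (ties: higher frequency).
#'
#' @param report a [enumerate_subsets()] report.
#' @param metrics a data frame (or list of [metric_set] objects) with one
#'   row per subset in `report`, containing at least `amlp`.
#' @return List with integer positions `top` and `optimal` into
#'   `report$subsets`.
#' @export
rank_subsets <- function(report, metrics) {
  stopifnot(inherits(report, "subset_report"))
  if (length(report$subsets) == 0L) stop("empty subset report")
  if (inherits(metrics, "data.frame")) {
    amlp <- metrics$amlp
  } else {
    amlp <- vapply(metrics, function(m) m$amlp, numeric(1))
  }
  if (length(amlp) != length(report$subsets))
    stop("'metrics' must have one entry per subset")
  sizes <- lengths(report$subsets)
  keys <- vapply(report$subsets, subset_lex_key, "")
  top <- order(-report$frequency, sizes, keys)[1]
  optimal <- order(amlp, -report$frequency)[1]
  list(top = top, optimal = optimal)
}
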