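## High-level pipeline: two-stage sampling, subset subdivision, and
## cross-validated subset scoring in one call.

#' Fit the full sparse Robit feature-selection pipeline
#'
#' Runs the two-stage restricted Gibbs / HMC fit, subdivides the stage-2
#' draws into posterior-mode-like feature subsets, optionally scores every
#' subset by leave-one-out cross-validation with the t-penalized logistic
#' model, and ranks the subsets (highest-frequency *top* subset, smallest
#' cross-validated AMLP *optimal* subset).
#'
#' @param x numeric feature matrix (samples x features) or a
#'   [robit_dataset()].
#' @param y binary labels (ignored when `x` is already a dataset).
#' @param cfg a [robit_config()].
#' @param settings stage-1 [sampler_settings()].
#' @param settings2 stage-2 settings (see [two_stage_fit()]).
#' @param rel_threshold per-draw relative magnitude threshold for the
#'   selection indicators.
#' @param min_freq minimum selection frequency below which a feature is
#'   treated as jitter.
#' @param loocv score each subset by LOOCV (can be slow for large n).
#' @param max_subsets evaluate at most this many subsets (the most
#'   frequent ones) by LOOCV; the report still lists all subsets.  The
#'   *optimal* subset is chosen among the evaluated ones.
#' @param covariates optional unpenalized feature indices, included in
#'   every LOOCV refit and excluded from the subset indicators.
#' @return An object of class `robit_hl` with elements `fit` (the
#'   [two_stage_fit()] result), `report` (subsets in original feature
#'   indices), `metrics` (list of [metric_set], or `NULL`), `ranks`
#'   (positions of the top/optimal subsets) and `data`.
#' @export
robit_hl <- function(x, y = NULL, cfg = robit_config(),
                     settings = sampler_settings(n_iter = 2000),
                     settings2 = NULL, rel_threshold = 0.1,
                     min_freq = 0.05, loocv = TRUE, max_subsets = 25,
                     covariates = NULL) {
  data <- if (inherits(x, "robit_dataset")) x else robit_dataset(x, y)
  if (!is.null(covariates)) settings$unpenalized <- covariates
  fit <- two_stage_fit(data, cfg, settings, settings2)

  draws <- fit$chain$beta_draws[, -1, drop = FALSE]
  sel <- fit$selected
  unpen2 <- fit$chain$settings$unpenalized
  keep2 <- setdiff(seq_along(sel), unpen2)
  ind <- indicator_matrix(draws[, keep2, drop = FALSE], rel_threshold)
  ind <- filter_low_frequency(ind, min_freq)
  rep2 <- enumerate_subsets(ind)

  ## map stage-2 column positions back to original feature indices
  report <- rep2
  report$subsets <- lapply(rep2$subsets, function(s) sel[keep2][s])
  report$discarded <- sel[keep2][rep2$discarded]
  report$feature_names <- data$feature_names

  metrics <- NULL
  ranks <- NULL
  if (length(report$subsets)) {
    if (loocv) {
      n_eval <- min(max_subsets, length(report$subsets))
      metrics <- lapply(report$subsets[seq_len(n_eval)], function(s)
        loocv_subset(data, s, covariates = covariates))
      eval_report <- report
      eval_report$subsets <- report$subsets[seq_len(n_eval)]
      eval_report$frequency <- report$frequency[seq_len(n_eval)]
      ranks <- rank_subsets(eval_report, metrics)
    } else {
      ranks <- list(top = order(-report$frequency,
                                lengths(report$subsets),
                                vapply(report$subsets, subset_lex_key,
                                       ""))[1],
                    optimal = NA_integer_)
    }
  }
  structure(list(fit = fit, report = report, metrics = metrics,
                 ranks = ranks, data = data),
            class = "robit_hl")
}

#' @export
print.robit_hl <- function(x, ...) {
  cat(sprintf("robit_hl fit: %d features screened to %d; %d feature subsets\n",
              x$data$p, length(x$fit$selected), length(x$report$subsets)))
  if (!is.null(x$ranks) && length(x$report$subsets)) {
    top <- x$report$subsets[[x$ranks$top]]
    cat("  top subset: {",
        paste(x$data$feature_names[top], collapse = ", "),
        sprintf("} freq %.3f\n", x$report$frequency[x$ranks$top]))
    if (!is.na(x$ranks$optimal) && !is.null(x$metrics)) {
      opt <- x$report$subsets[[x$ranks$optimal]]
      cat("  optimal subset: {",
          paste(x$data$feature_names[opt], collapse = ", "),
          sprintf("} AMLP %.3f\n", x$metrics[[x$ranks$optimal]]$amlp))
    }
  }
  invisible(x)
}

#' @rdname robit_hl
#' @param object a fitted `robit_hl` object.
#' @param newdata raw feature matrix with all original columns.
#' @param ... unused.
#' @export
predict.robit_hl <- function(object, newdata, ...) {
  predict(object$fit, newdata)
}
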