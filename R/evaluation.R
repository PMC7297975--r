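## Cross-validatory scoring of feature subsets with a t-penalized logistic
## model, and the four predictive metrics (ER, AMLP, AUROC, AUPRC).

log1pexp <- function(m) ifelse(m > 0, m + log1p(exp(-m)), log1p(exp(m)))

## penalized logistic objective, gradient, Hessian diagonal of the penalty
plr_objective <- function(beta, X, y, df, scale) {
  m <- drop(X %*% beta)
  ll <- sum(y * m - log1pexp(m))
  b <- beta[-1]
  pen <- sum(lgamma((df + 1) / 2) - lgamma(df / 2) -
               0.5 * log(df * pi * scale^2) -
               ((df + 1) / 2) * log1p(b^2 / (df * scale^2)))
  ll + pen
}

plr_grad <- function(beta, X, y, df, scale) {
  m <- drop(X %*% beta)
  g <- drop(crossprod(X, y - plogis(m)))
  b <- beta[-1]
  g[-1] <- g[-1] - (df + 1) * b / (df * scale^2 + b^2)
  g
}

## one damped-Newton pass with backtracking; returns the local optimum found
plr_newton <- function(beta, X, y, df, scale, ridge = 0, max_iter = 200,
                       tol = 1e-8) {
  obj <- function(b) plr_objective(b, X, y, df, scale) -
    ridge * sum(b[-1]^2) / 2
  k <- ncol(X)
  f <- obj(beta)
  for (it in seq_len(max_iter)) {
    m <- drop(X %*% beta)
    pr <- plogis(m)
    g <- drop(crossprod(X, y - pr))
    b <- beta[-1]
    g[-1] <- g[-1] - (df + 1) * b / (df * scale^2 + b^2) - ridge * b
    w <- pr * (1 - pr)
    H <- -crossprod(X * w, X)
    ph <- (df + 1) * (df * scale^2 - b^2) / (df * scale^2 + b^2)^2
    diagH <- c(0, -ph - ridge)
    diag(H) <- diag(H) + diagH
    ## damp until the (negated) Hessian is usable and the step ascends
    damp <- 1e-8
    repeat {
      A <- -H + diag(damp, k)
      step <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step)) && sum(step * g) > 0) break
      damp <- damp * 10
      if (damp > 1e8) { step <- g; break }   # gradient fallback
    }
    t_ls <- 1
    f_new <- obj(beta + t_ls * step)
    while ((!is.finite(f_new) || f_new < f) && t_ls > 1e-12) {
      t_ls <- t_ls / 2
      f_new <- obj(beta + t_ls * step)
    }
    if (!is.finite(f_new) || f_new < f) break
    beta <- beta + t_ls * step
    converged <- sqrt(sum(g^2)) < 1e-6
    f_old <- f; f <- f_new
    if (converged || abs(f - f_old) < tol) break
  }
  list(beta = beta, objective = obj(beta),
       grad_norm = sqrt(sum(plr_grad(beta, X, y, df, scale)^2)))
}

#' Logistic regression with a Student-t penalty
#'
#' Maximizes the logistic log-likelihood plus the log of a scaled-t density
#' (default Cauchy, `penalty_df = 1`) on every non-intercept coefficient;
#' the intercept is unpenalized.  The penalty is non-convex, so the damped
#' Newton optimizer is restarted from zero and from a ridge-regularized
#' solution, keeping the better penalized objective.  The heavy-tailed
#' penalty keeps the optimum finite even for separable data.
#'
#' @param X n x (k+1) design matrix including a leading intercept column.
#' @param y binary labels in \{0, 1\}.
#' @param penalty_df degrees of freedom of the t penalty (default 1).
#' @param penalty_scale scale of the t penalty (default 1).
#' @return List with `beta`, `objective`, `grad_norm` and `converged`
#'   (`grad_norm < 1e-6`).
#' @export
fit_plr_t_penalty <- function(X, y, penalty_df = 1, penalty_scale = 1) {
  X <- as.matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2 && nrow(X) > 0) {
    ## single-class fold: the penalty still regularizes; proceed
  }
  k <- ncol(X)
  fit0 <- plr_newton(numeric(k), X, y, penalty_df, penalty_scale)
  ridge_start <- plr_newton(numeric(k), X, y, penalty_df, 1e6,
                            ridge = 1)$beta
  fit1 <- plr_newton(ridge_start, X, y, penalty_df, penalty_scale)
  best <- if (fit1$objective > fit0$objective) fit1 else fit0
  best$beta <- unname(best$beta)
  best$converged <- best$grad_norm < 1e-6
  best
}

#' Average minus log predictive probability
#'
#' Mean of `-log(P_hat_i(y_i))` over cases, the cross-entropy-style score
#' that punishes confident misclassification.  Probabilities of exactly 0
#' are clipped at `1e-300`.
#'
#' @param prob_true predictive probabilities assigned to the observed
#'   labels, in (0, 1].
#' @return A single non-negative number (nats).
#' @export
amlp <- function(prob_true) {
  if (any(prob_true < 0 | prob_true > 1)) stop("probabilities must be in [0, 1]")
  mean(-log(pmax(prob_true, 1e-300)))
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic of the scores (ties counted 1/2), computed via
#' the pROC package.
#'
#' @param scores numeric prediction scores (higher = class 1).
#' @param labels binary labels in \{0, 1\}.
#' @return AUROC in \[0, 1\]; `NA` with a warning if only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the PR step curve is integrated as
#' `sum((R_k - R_{k-1}) * P_k)` over distinct score thresholds, with no
#' trapezoidal interpolation between points.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` with a warning if no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) {
    warning("AUPRC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- c(s[-1] != s[-length(s)], TRUE)   # ends of tied blocks
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * prec)
}

#' Bundle the four predictive metrics
#'
#' @param prob1 predictive probabilities of class 1, one per case.
#' @param y observed binary labels.
#' @return An object of class `metric_set` with `error_rate` (at the 0.5
#'   cut), `amlp`, `auroc` and `auprc`.
#' @export
metric_set <- function(prob1, y) {
  y <- as.integer(y)
  p_true <- ifelse(y == 1L, prob1, 1 - prob1)
  structure(list(error_rate = mean((prob1 > 0.5) != (y == 1L)),
                 amlp = amlp(p_true),
                 auroc = auroc(prob1, y),
                 auprc = auprc(prob1, y)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ER %.3f | AMLP %.3f | AUROC %.3f | AUPRC %.3f\n",
              x$error_rate, x$amlp, x$auroc, x$auprc))
  invisible(x)
}

#' Leave-one-out cross-validated metrics of a feature subset
#'
#' For each case, fits the t-penalized logistic model on the remaining
#' cases restricted to the subset (plus any covariate columns), predicts
#' the held-out case, and scores the collected probabilities with
#' [metric_set()].
#'
#' @param data a [robit_dataset()].
#' @param subset integer feature indices (non-empty).
#' @param covariates optional extra feature indices always included.
#' @param penalty_df,penalty_scale t-penalty parameters passed to
#'   [fit_plr_t_penalty()].
#' @return A [metric_set] with attribute `"probabilities"` holding the
#'   per-case LOOCV probabilities.
#' @export
loocv_subset <- function(data, subset, covariates = NULL,
                         penalty_df = 1, penalty_scale = 1) {
  stopifnot(inherits(data, "robit_dataset"), length(subset) >= 1)
  if (data$n < 3) stop("need at least 3 cases for LOOCV")
  cols <- c(1L, sort(unique(c(subset, covariates))) + 1L)
  X <- data$X[, cols, drop = FALSE]
  y <- data$y
  probs <- vapply(seq_len(data$n), function(i) {
    fit <- fit_plr_t_penalty(X[-i, , drop = FALSE], y[-i],
                             penalty_df, penalty_scale)
    plogis(sum(X[i, ] * fit$beta))
  }, numeric(1))
  out <- metric_set(probs, y)
  attr(out, "probabilities") <- probs
  out
}
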