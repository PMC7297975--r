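## Robit likelihood core: scaled-t CDF, stable log-CDF, log-likelihood,
## conditional negative log posterior + gradient, posterior-averaged prediction.

#' Model hyperparameter configuration
#'
#' Fixed hyperparameters of the Robit model and of the Cauchy coefficient
#' prior.  The latent noise of the Robit link is a scaled Student-t with
#' `alpha0` degrees of freedom and squared scale `omega0`; each penalized
#' coefficient has a scaled-t prior with `alpha1` degrees of freedom and
#' squared scale `omega1` (for `alpha1 = 1` this is a Cauchy prior with scale
#' `sqrt(omega1)`).
#'
#' The defaults fix the link at a Cauchy noise distribution (`alpha0 = 1`),
#' with `omega0 = 0.5` so that the link resembles the logistic near the
#' origin but has heavier tails, and a Cauchy coefficient prior with scale
#' `exp(-5)`, i.e. `omega1 = exp(-10)`.  Only `beta / sqrt(omega0)` is
#' identifiable, so `omega0` is a convention, not a tunable parameter.
#'
#' @param alpha0 degrees of freedom of the noise t-distribution (> 0).
#' @param omega0 squared scale of the noise t-distribution (> 0).
#' @param alpha1 degrees of freedom of the coefficient prior (> 0).
#' @param omega1 squared scale of the coefficient prior (> 0).
#' @return An object of class `robit_config`.
#' @export
#' @examples
#' cfg <- robit_config()
#' sqrt(cfg$omega1)  # exp(-5)
robit_config <- function(alpha0 = 1, omega0 = 0.5,
                         alpha1 = 1, omega1 = exp(-10)) {
  for (nm in c("alpha0", "omega0", "alpha1", "omega1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  structure(list(alpha0 = alpha0, omega0 = omega0,
                 alpha1 = alpha1, omega1 = omega1),
            class = "robit_config")
}

#' Construct a classification dataset with an intercept column
#'
#' @param x numeric matrix, samples in rows, features in columns (no
#'   intercept column; it is prepended here).
#' @param y binary response, values in \{0, 1\}, length `nrow(x)`.
#' @param feature_names optional character vector of feature identifiers;
#'   defaults to the column names of `x` or `f1, f2, ...`.
#' @return An object of class `robit_dataset` with elements `X` (design
#'   matrix including the leading all-ones column), `y`, `feature_names`,
#'   `n` and `p`.
#' @export
robit_dataset <- function(x, y, feature_names = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x)) stop("'x' contains missing values")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("'y' must contain only 0/1")
  p <- ncol(x)
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  }
  if (length(feature_names) != p)
    stop("'feature_names' must have one entry per feature")
  X <- cbind(1, x)
  colnames(X) <- c("(Intercept)", feature_names)
  structure(list(X = X, y = y, feature_names = feature_names,
                 n = nrow(X), p = p),
            class = "robit_dataset")
}

#' @export
print.robit_dataset <- function(x, ...) {
  cat(sprintf("robit_dataset: %d cases x %d features (+ intercept), %d/%d in class 1/0\n",
              x$n, x$p, sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' CDF of the scaled Student-t distribution
#'
#' Distribution function of a zero-mean t variable with `alpha` degrees of
#' freedom and scale `sqrt(omega)`.  For `alpha = 1` (Cauchy) the closed
#' form `1/2 + atan(x / sqrt(omega)) / pi` is used; otherwise the standard
#' t CDF of `x / sqrt(omega)` is evaluated.
#'
#' @param x numeric vector of quantiles.
#' @param alpha degrees of freedom (> 0).
#' @param omega squared scale (> 0).
#' @return Probabilities in (0, 1), same length as `x`.
#' @export
#' @examples
#' student_t_cdf(0, 1, 0.5)          # 0.5
#' student_t_cdf(sqrt(0.5), 1, 0.5)  # 0.75
student_t_cdf <- function(x, alpha, omega) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a single positive number")
  u <- x / sqrt(omega)
  if (alpha == 1) 0.5 + atan(u) / pi else pt(u, df = alpha)
}

#' Numerically safe log-CDF of the scaled Student-t
#'
#' Evaluates `log(student_t_cdf(x, alpha, omega))` without underflow in the
#' left tail.  For `alpha = 1` the exact identity
#' `T(x) = atan(-1/u) / pi` for `u = x/sqrt(omega) < 0` keeps the log finite
#' down to astronomically negative `x`; the right tail uses `log1p`.
#'
#' @inheritParams student_t_cdf
#' @return Log-probabilities, same length as `x`.
#' @export
student_t_log_cdf <- function(x, alpha, omega) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a single positive number")
  u <- x / sqrt(omega)
  if (alpha == 1) {
    out <- numeric(length(u))
    neg <- u < 0
    out[neg] <- log(atan(-1 / u[neg])) - log(pi)
    out[!neg & u == 0] <- log(0.5)
    pos <- u > 0
    out[pos] <- log1p(-atan(1 / u[pos]) / pi)
    out
  } else {
    pt(u, df = alpha, log.p = TRUE)
  }
}

## log density of the scaled t (alpha = 1 i.e. Cauchy handled exactly)
student_t_log_pdf <- function(x, alpha, omega) {
  u <- x / sqrt(omega)
  if (alpha == 1) {
    -log(pi * sqrt(omega)) - log1p(u^2)
  } else {
    dt(u, df = alpha, log = TRUE) - 0.5 * log(omega)
  }
}

#' Robit log-likelihood
#'
#' Sum over cases of `y_i * log T(x_i beta) + (1 - y_i) * log T(-x_i beta)`
#' where `T` is the scaled-t CDF of the noise distribution.  Evaluated with
#' the numerically safe log-CDF so that linear predictors up to about `1e6`
#' in magnitude stay finite.
#'
#' @param beta coefficient vector of length `p + 1` (intercept first).
#' @param data a [robit_dataset()].
#' @param cfg a [robit_config()].
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(beta, data, cfg = robit_config()) {
  stopifnot(inherits(data, "robit_dataset"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$X))
    stop(sprintf("'beta' has length %d but the design has %d columns",
                 length(beta), ncol(data$X)))
  m <- drop(data$X %*% beta)
  s <- ifelse(data$y == 1L, 1, -1)
  sum(student_t_log_cdf(s * m, cfg$alpha0, cfg$omega0))
}

## Per-case gradient weights of the NEGATIVE log-likelihood wrt the linear
## predictor m: w_i = t(m_i) / (1 - y_i - T(m_i)), computed on the log scale
## for tail stability.
robit_grad_weights <- function(m, y, cfg) {
  s <- ifelse(y == 1L, 1, -1)
  lt <- student_t_log_pdf(m, cfg$alpha0, cfg$omega0)
  lT <- student_t_log_cdf(s * m, cfg$alpha0, cfg$omega0)
  -s * exp(lt - lT)
}

#' Conditional negative log posterior and its gradient over the active block
#'
#' Energy function used by the Hamiltonian Monte Carlo update: minus the
#' Robit log-likelihood at the full linear predictor
#' `X_U beta_U + X_F beta_F` minus the Gaussian log-prior terms
#' `-beta_j^2 / (2 lambda_j)` for the active coordinates `j` in `U`, up to
#' an additive constant (terms depending only on `lambda` are dropped).  The
#' gradient component for `j` in `U` is the likelihood term plus
#' `beta_j / lambda_j`.
#'
#' The frozen contribution `X_F beta_F` may be supplied precomputed via
#' `cached_xf_betaf`, in which case it is used as-is and never recomputed;
#' this is the cache exploited by the restricted Gibbs sampler.
#'
#' @param beta_u active coefficients, aligned with `u`.
#' @param beta_f frozen coefficients, aligned with the complement of `u`.
#' @param lambda_u prior variances of the active coefficients (> 0).
#' @param data a [robit_dataset()].
#' @param cfg a [robit_config()].
#' @param u integer column indices of the design matrix forming the active
#'   set (1 is the intercept column).  Defaults to all columns.
#' @param cached_xf_betaf optional length-`n` precomputed `X_F beta_F`.
#' @return A list with `energy` (a number) and `gradient` (length of `u`).
#' @export
neg_log_posterior_and_gradient <- function(beta_u, beta_f = numeric(0),
                                           lambda_u, data,
                                           cfg = robit_config(),
                                           u = seq_len(ncol(data$X)),
                                           cached_xf_betaf = NULL) {
  stopifnot(inherits(data, "robit_dataset"))
  u <- as.integer(u)
  f <- setdiff(seq_len(ncol(data$X)), u)
  if (length(beta_u) != length(u) || length(lambda_u) != length(u))
    stop("'beta_u' and 'lambda_u' must align with 'u'")
  if (any(lambda_u <= 0)) stop("'lambda_u' must be positive")
  if (is.null(cached_xf_betaf)) {
    cached_xf_betaf <- if (length(f))
      drop(data$X[, f, drop = FALSE] %*% beta_f) else numeric(data$n)
  }
  XU <- data$X[, u, drop = FALSE]
  m <- cached_xf_betaf + drop(XU %*% beta_u)
  s <- ifelse(data$y == 1L, 1, -1)
  nll <- -sum(student_t_log_cdf(s * m, cfg$alpha0, cfg$omega0))
  energy <- nll + sum(beta_u^2 / (2 * lambda_u))
  w <- robit_grad_weights(m, data$y, cfg)
  grad <- drop(crossprod(XU, w)) + beta_u / lambda_u
  list(energy = energy, gradient = grad)
}

#' Posterior-averaged predictive probability
#'
#' Averages the Robit predictive probability `T(x beta)` over the retained
#' MCMC draws of the coefficients.
#'
#' @param chain a [robit_chain] (see [run_mcmc()]), or any object with a
#'   `beta_draws` matrix.
#' @param x_new a numeric vector including the leading intercept element, or
#'   a matrix of such rows, on the same scale as the chain's design matrix.
#' @param cfg a [robit_config()].
#' @return Predictive probabilities of class 1, one per row of `x_new`.
#' @export
posterior_average_prediction <- function(chain, x_new, cfg = robit_config()) {
  B <- chain$beta_draws
  if (is.null(B) || nrow(B) == 0L) stop("chain contains no retained draws")
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1L)
  if (ncol(x_new) != ncol(B))
    stop("'x_new' must have one column per chain coefficient (intercept first)")
  M <- x_new %*% t(B)                      # cases x draws
  P <- student_t_cdf(M, cfg$alpha0, cfg$omega0)
  rowMeans(P)
}
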