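## Restricted Gibbs sampling with HMC over the active coefficient block,
## and the two-stage (screen-then-refit) fitting procedure.

#' Sampler settings
#'
#' Tuning parameters of the restricted Gibbs / HMC sampler.
#'
#' @param n_iter total Gibbs iterations.
#' @param n_burnin discarded iterations; defaults to half of `n_iter`.
#' @param update_fraction target fraction of coefficients refreshed by HMC
#'   per iteration.  The threshold `eta` on the freshly drawn latent
#'   variances is the corresponding order statistic, so exactly
#'   `ceiling(update_fraction * p)` features (plus the intercept) are active.
#' @param leapfrog_steps number of leapfrog steps per HMC trajectory.
#' @param step_size leapfrog step size, or `"auto"` to adapt it during
#'   burn-in toward `target_accept` by a Robbins-Monro update and then
#'   freeze it.
#' @param target_accept acceptance-rate target for step-size adaptation.
#' @param p_star number of features kept after the screening stage of
#'   [two_stage_fit()].
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param lambda0 fixed prior variance of the intercept (and of any
#'   unpenalized covariates); large so these are effectively unpenalized.
#' @param standardize standardize features to zero mean / unit variance
#'   internally before sampling (coefficients are reported on the
#'   standardized scale).  A fixed prior scale only means something relative
#'   to a common feature scale.
#' @param unpenalized optional integer vector of feature indices treated as
#'   unpenalized covariates: their prior variance is fixed at `lambda0`,
#'   they are always in the HMC update set, and they bypass screening and
#'   subset indicators.
#' @param verbose report iteration, running acceptance rate, active-set
#'   size and log-posterior every `verbose` iterations (0 = silent).
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(n_iter = 2000, n_burnin = NULL,
                             update_fraction = 0.1, leapfrog_steps = 50,
                             step_size = "auto", target_accept = 0.8,
                             p_star = 100, thin = 1, seed = NULL,
                             lambda0 = 100, standardize = TRUE,
                             unpenalized = NULL, verbose = 0) {
  if (is.null(n_burnin)) n_burnin <- floor(n_iter / 2)
  stopifnot(n_iter >= 1, n_burnin >= 0, n_burnin < n_iter,
            update_fraction > 0, update_fraction <= 1,
            leapfrog_steps >= 1, p_star >= 1, thin >= 1, lambda0 > 0)
  if (!identical(step_size, "auto"))
    stopifnot(is.numeric(step_size), step_size >= 0)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 update_fraction = update_fraction,
                 leapfrog_steps = as.integer(leapfrog_steps),
                 step_size = step_size, target_accept = target_accept,
                 p_star = as.integer(p_star), thin = as.integer(thin),
                 seed = seed, lambda0 = lambda0, standardize = standardize,
                 unpenalized = unpenalized, verbose = as.integer(verbose)),
            class = "sampler_settings")
}

#' Select the restricted update set from freshly drawn latent variances
#'
#' The coefficients refreshed by HMC in an iteration are those whose latent
#' prior variance, drawn in the immediately preceding Gibbs step, is among
#' the `ceiling(fraction * p)` largest; ties are broken in favour of the
#' lower feature index.  The choice depends only on the latent variances,
#' never on the current coefficient values, which is what keeps the
#' restricted update a valid Markov transition.  The intercept is always
#' included.
#'
#' @param lambda_hat per-feature latent variances (length `p`, intercept
#'   excluded).
#' @param fraction fraction of features to update, in (0, 1].
#' @return Sorted integer design-column indices: 1 (the intercept) plus
#'   `feature index + 1` for each selected feature.
#' @export
select_update_set <- function(lambda_hat, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  p <- length(lambda_hat)
  m <- min(p, ceiling(fraction * p))
  ord <- order(lambda_hat, decreasing = TRUE)  # stable: ties by lower index
  sort(c(1L, ord[seq_len(m)] + 1L))
}

#' One leapfrog trajectory for the active coefficient block
#'
#' Integrates Hamiltonian dynamics of the conditional negative log posterior
#' of `beta_u` (frozen contribution `m_fixed = X_F beta_F` held in the
#' cache) for `n_steps` leapfrog steps of size `step_size`, starting from
#' the supplied momentum.  Deterministic given its inputs; the Cauchy-link
#' case runs in compiled code.
#'
#' @param beta_u starting active coefficients.
#' @param momentum starting momentum (same length).
#' @param xu active design columns (n x k).
#' @param m_fixed cached frozen linear predictor `X_F beta_F`, length n.
#' @param y binary labels.
#' @param lambda_u prior variances of the active coefficients.
#' @param cfg a [robit_config()].
#' @param step_size leapfrog step size (0 gives the identity map).
#' @param n_steps number of leapfrog steps.
#' @param inv_mass inverse of the diagonal mass matrix (the position step
#'   for coordinate `j` is `step_size * inv_mass[j] * p[j]`); defaults to
#'   the identity.
#' @return List with `beta`, `momentum` (final, not negated), `energy0`,
#'   `energy1` (potential energies at the ends) and `ok` (FALSE if the
#'   trajectory hit a non-finite energy).
#' @export
leapfrog_trajectory <- function(beta_u, momentum, xu, m_fixed, y, lambda_u,
                                cfg = robit_config(), step_size, n_steps,
                                inv_mass = rep(1, length(beta_u))) {
  if (cfg$alpha0 == 1) {
    cpp_leapfrog_cauchy(xu, m_fixed, as.integer(y), as.numeric(beta_u),
                        as.numeric(momentum), as.numeric(lambda_u),
                        cfg$omega0, step_size, as.integer(n_steps),
                        as.numeric(inv_mass))
  } else {
    leapfrog_r(beta_u, momentum, xu, m_fixed, y, lambda_u, cfg,
               step_size, n_steps, inv_mass)
  }
}

## reference leapfrog in R, any alpha0 (used when the link is not Cauchy)
leapfrog_r <- function(beta_u, momentum, xu, m_fixed, y, lambda_u, cfg,
                       step_size, n_steps,
                       inv_mass = rep(1, length(beta_u))) {
  eg <- function(b) {
    m <- m_fixed + drop(xu %*% b)
    s <- ifelse(y == 1L, 1, -1)
    nll <- -sum(student_t_log_cdf(s * m, cfg$alpha0, cfg$omega0))
    w <- robit_grad_weights(m, y, cfg)
    list(energy = nll + sum(b^2 / (2 * lambda_u)),
         gradient = drop(crossprod(xu, w)) + b / lambda_u)
  }
  b <- unname(as.numeric(beta_u)); mom <- unname(as.numeric(momentum))
  cur <- eg(b)
  energy0 <- energy1 <- cur$energy
  ok <- is.finite(energy0)
  if (ok && step_size > 0 && n_steps > 0) {
    mom <- mom - 0.5 * step_size * cur$gradient
    for (l in seq_len(n_steps)) {
      b <- b + step_size * inv_mass * mom
      cur <- eg(b)
      energy1 <- cur$energy
      if (!is.finite(energy1)) { ok <- FALSE; break }
      f <- if (l == n_steps) 0.5 else 1
      mom <- mom - f * step_size * cur$gradient
    }
  }
  list(beta = unname(b), momentum = unname(mom), energy0 = energy0,
       energy1 = energy1, ok = ok)
}

#' One HMC update of the active coefficients
#'
#' Draws standard-normal momenta, runs a leapfrog trajectory on the
#' conditional posterior of `beta[u]` with the remaining coefficients
#' frozen, and accepts or rejects by the Metropolis rule on the Hamiltonian.
#' Frozen coefficients are never modified; a trajectory that reaches a
#' non-finite energy is rejected.
#'
#' @param beta full coefficient vector (length p + 1, intercept first).
#' @param lambda full prior-variance vector aligned with `beta`.
#' @param u active design-column indices (see [select_update_set()]).
#' @param data a [robit_dataset()]; its design matrix is used as-is.
#' @param cfg a [robit_config()].
#' @param step_size leapfrog step size.
#' @param leapfrog_steps number of leapfrog steps.
#' @param cached_xf_betaf optional cached `X_F beta_F` (length n).
#' @param inv_mass inverse diagonal mass matrix over `u` (default
#'   identity); momenta are drawn as `N(0, mass)`.
#' @return List with the updated `beta`, `accepted` flag, `delta_h`, and
#'   `accept_prob`.
#' @export
hmc_update <- function(beta, lambda, u, data, cfg = robit_config(),
                       step_size, leapfrog_steps, cached_xf_betaf = NULL,
                       inv_mass = rep(1, length(u))) {
  stopifnot(inherits(data, "robit_dataset"))
  u <- as.integer(u)
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  X <- data$X
  xu <- X[, u, drop = FALSE]
  if (is.null(cached_xf_betaf)) {
    f <- setdiff(seq_len(ncol(X)), u)
    cached_xf_betaf <- if (length(f))
      drop(X[, f, drop = FALSE] %*% beta[f]) else numeric(data$n)
  }
  mom <- rnorm(length(u)) / sqrt(inv_mass)
  traj <- leapfrog_trajectory(beta[u], mom, xu, cached_xf_betaf, data$y,
                              lambda[u], cfg, step_size, leapfrog_steps,
                              inv_mass)
  k0 <- sum(mom^2 * inv_mass) / 2
  k1 <- sum(traj$momentum^2 * inv_mass) / 2
  delta_h <- (traj$energy1 + k1) - (traj$energy0 + k0)
  accept_prob <- if (!traj$ok || !is.finite(delta_h)) 0 else min(1, exp(-delta_h))
  accepted <- runif(1) < accept_prob
  if (accepted) beta[u] <- traj$beta
  list(beta = beta, accepted = accepted, delta_h = delta_h,
       accept_prob = accept_prob)
}

#' Run the restricted Gibbs / HMC sampler
#'
#' Iterates the sampler: (1) redraw every latent variance from its
#' inverse-gamma conditional given the current coefficient; (2) form the
#' active set from the freshly drawn variances only; (3) update the active
#' coefficients by one HMC trajectory with the frozen linear predictor
#' `X_F beta_F` cached; (4) commit, retaining post-burn-in draws.
#' Identical seeds give identical chains.
#'
#' @param data a [robit_dataset()].
#' @param cfg a [robit_config()].
#' @param settings a [sampler_settings()].
#' @return An object of class `robit_chain`: `beta_draws` (R x (p+1)),
#'   `lambda_draws` (R x p), `accept_rate`, `log_post` (retained
#'   unnormalized log joint posterior), `step_size` (final, after
#'   adaptation), `feature_names`, standardization `center`/`scale`, and
#'   the settings and configuration used.
#' @export
run_mcmc <- function(data, cfg = robit_config(),
                     settings = sampler_settings()) {
  stopifnot(inherits(data, "robit_dataset"),
            inherits(settings, "sampler_settings"))
  if (data$n < 2) stop("need at least 2 cases")
  if (length(unique(data$y)) < 2)
    stop("labels are degenerate: both classes must be present")
  if (!is.null(settings$seed)) set.seed(settings$seed)

  n <- data$n; p <- data$p
  unpen <- as.integer(settings$unpenalized %||% integer(0))
  if (length(unpen) && (any(unpen < 1) || any(unpen > p)))
    stop("'unpenalized' indices out of range")
  pen <- setdiff(seq_len(p), unpen)

  if (settings$standardize) {
    center <- colMeans(data$X[, -1, drop = FALSE])
    scl <- apply(data$X[, -1, drop = FALSE], 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- cbind(1, sweep(sweep(data$X[, -1, drop = FALSE], 2, center), 2,
                        scl, "/"))
  } else {
    center <- rep(0, p); scl <- rep(1, p)
    X <- data$X
  }
  sdata <- data
  sdata$X <- X

  beta <- numeric(p + 1)
  lambda_feat <- sample_lambda_prior(p, cfg)
  lambda_feat[unpen] <- settings$lambda0
  m_full <- numeric(n)
  ## diagonal mass: conditional prior curvature 1/lambda plus a
  ## logistic-style bound on the likelihood curvature
  lik_curv <- 0.25 * colSums(X^2)

  adapt <- identical(settings$step_size, "auto")
  eps <- if (adapt) 0.1 else settings$step_size
  log_eps <- log(max(eps, 1e-12))

  n_keep <- floor((settings$n_iter - settings$n_burnin) / settings$thin)
  beta_draws <- matrix(NA_real_, n_keep, p + 1)
  lambda_draws <- matrix(NA_real_, n_keep, p)
  log_post <- numeric(n_keep)
  kept <- 0L
  n_accept <- 0L

  for (t in seq_len(settings$n_iter)) {
    ## Step 1: Gibbs refresh of all latent variances
    lambda_feat[pen] <- sample_lambda_given_beta(beta[pen + 1L], cfg)[seq_along(pen)]
    ## Step 2: active set from the fresh variances only
    u <- select_update_set(lambda_feat, settings$update_fraction)
    if (length(unpen)) u <- sort(union(u, unpen + 1L))
    lambda_full <- c(settings$lambda0, lambda_feat)
    ## Step 3: HMC on beta_U with X_F beta_F cached
    xu <- X[, u, drop = FALSE]
    m_u <- drop(xu %*% beta[u])
    m_fixed <- m_full - m_u
    inv_mass <- 1 / (1 / lambda_full[u] + lik_curv[u])
    mom <- rnorm(length(u)) / sqrt(inv_mass)
    traj <- leapfrog_trajectory(beta[u], mom, xu, m_fixed, data$y,
                                lambda_full[u], cfg, eps,
                                settings$leapfrog_steps, inv_mass)
    delta_h <- (traj$energy1 + sum(traj$momentum^2 * inv_mass) / 2) -
      (traj$energy0 + sum(mom^2 * inv_mass) / 2)
    accept_prob <- if (!traj$ok || !is.finite(delta_h)) 0 else
      min(1, exp(-delta_h))
    if (runif(1) < accept_prob) {
      beta[u] <- traj$beta
      n_accept <- n_accept + 1L
    }
    ## Step 4: commit, refresh the cache
    m_full <- m_fixed + drop(xu %*% beta[u])
    if (t %% 100L == 0L) m_full <- drop(X %*% beta)  # wash out drift

    if (settings$verbose > 0L && t %% settings$verbose == 0L) {
      s <- ifelse(data$y == 1L, 1, -1)
      message(sprintf(
        "iter %d/%d | accept %.2f | |U| %d | step %.3g | log-post %.1f",
        t, settings$n_iter, n_accept / t, length(u), eps,
        sum(student_t_log_cdf(s * m_full, cfg$alpha0, cfg$omega0)) -
          sum(beta^2 / (2 * lambda_full))))
    }

    if (adapt && t <= settings$n_burnin) {
      log_eps <- log_eps + 0.5 * (accept_prob - settings$target_accept) /
        t^0.6
      eps <- exp(max(min(log_eps, log(10)), log(1e-8)))
    }

    if (t > settings$n_burnin &&
        (t - settings$n_burnin) %% settings$thin == 0L) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      lambda_draws[kept, ] <- lambda_feat
      s <- ifelse(data$y == 1L, 1, -1)
      log_post[kept] <- sum(student_t_log_cdf(s * m_full, cfg$alpha0,
                                              cfg$omega0)) -
        sum(beta^2 / (2 * lambda_full)) - 0.5 * sum(log(lambda_full)) +
        sum(lambda_prior_logpdf(lambda_feat[pen], cfg))
    }
  }

  colnames(beta_draws) <- c("(Intercept)", data$feature_names)
  colnames(lambda_draws) <- data$feature_names
  structure(list(beta_draws = beta_draws, lambda_draws = lambda_draws,
                 accept_rate = n_accept / settings$n_iter,
                 log_post = log_post, step_size = eps,
                 feature_names = data$feature_names,
                 center = center, scale = scl,
                 settings = settings, cfg = cfg),
            class = "robit_chain")
}

#' @export
print.robit_chain <- function(x, ...) {
  cat(sprintf("robit_chain: %d retained draws, %d coefficients, accept rate %.2f, step size %.4g\n",
              nrow(x$beta_draws), ncol(x$beta_draws), x$accept_rate,
              x$step_size))
  invisible(x)
}

#' Predict from a fitted chain
#'
#' Applies the chain's stored standardization to new raw feature rows,
#' prepends the intercept, and averages the Robit predictive probability
#' over the retained draws.
#'
#' @param object a `robit_chain`.
#' @param newdata numeric matrix of raw feature values, columns matching the
#'   features the chain was fitted on.
#' @param ... unused.
#' @return Predictive probabilities of class 1.
#' @export
predict.robit_chain <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("'newdata' must have one column per fitted feature")
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  posterior_average_prediction(object, cbind(1, z), object$cfg)
}

#' Two-stage fit: screen on all features, refit on the top set
#'
#' Stage 1 runs the restricted Gibbs / HMC sampler on all `p` features and
#' ranks them by the absolute value of the posterior mean coefficient.
#' Stage 2 reruns the sampler on the top `min(p_star, p)` features (the
#' intercept and any unpenalized covariates are always retained).  Feature
#' selection and prediction are based on the stage-2 chain; the original
#' feature indices are preserved in its names.
#'
#' @param data a [robit_dataset()].
#' @param cfg a [robit_config()].
#' @param settings stage-1 [sampler_settings()]; its `p_star` sets the
#'   screening size.
#' @param settings2 stage-2 settings; defaults to the stage-1 settings with
#'   `n_iter = 5000` and, when a seed was given, `seed + 1`.
#' @return An object of class `robit_two_stage` with the stage-2 `chain`,
#'   `selected` (original indices of screened features), and
#'   `stage1_means` (stage-1 posterior mean coefficients, features only).
#' @export
two_stage_fit <- function(data, cfg = robit_config(),
                          settings = sampler_settings(n_iter = 2000),
                          settings2 = NULL) {
  stopifnot(inherits(data, "robit_dataset"))
  if (is.null(settings2)) {
    settings2 <- settings
    settings2$n_iter <- 5000L
    settings2$n_burnin <- 2500L
    if (!is.null(settings$seed)) settings2$seed <- settings$seed + 1L
  }
  stage1 <- run_mcmc(data, cfg, settings)
  means <- colMeans(stage1$beta_draws)[-1]
  unpen <- as.integer(settings$unpenalized %||% integer(0))
  rankable <- setdiff(seq_len(data$p), unpen)
  ord <- rankable[order(abs(means[rankable]), decreasing = TRUE)]
  sel <- sort(c(unpen, ord[seq_len(min(settings$p_star, length(ord)))]))
  data2 <- robit_dataset(data$X[, sel + 1L, drop = FALSE], data$y,
                         feature_names = data$feature_names[sel])
  if (length(unpen)) settings2$unpenalized <- match(unpen, sel)
  chain <- run_mcmc(data2, cfg, settings2)
  structure(list(chain = chain, selected = sel, stage1_means = means,
                 stage1_accept_rate = stage1$accept_rate,
                 feature_names = data$feature_names),
            class = "robit_two_stage")
}

#' @export
print.robit_two_stage <- function(x, ...) {
  cat(sprintf("robit_two_stage: %d screened features; stage-2 chain with %d draws (accept rate %.2f)\n",
              length(x$selected), nrow(x$chain$beta_draws),
              x$chain$accept_rate))
  invisible(x)
}

#' @rdname two_stage_fit
#' @param object a `robit_two_stage` fit.
#' @param newdata raw feature matrix with all original `p` columns (or
#'   exactly the screened columns).
#' @param ... unused.
#' @export
predict.robit_two_stage <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(object$feature_names))
    newdata <- newdata[, object$selected, drop = FALSE]
  predict(object$chain, newdata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
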