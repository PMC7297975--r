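## Latent-factor simulation designs with grouped signal features, used for
## benchmarking within-group selection and prediction.

#' Specify a grouped latent-factor simulation
#'
#' Signal features are generated as linear combinations of per-case latent
#' factors plus idiosyncratic Gaussian noise; the remaining features are
#' independent standard normal noise.  Two label rules are supported:
#' `"factor-threshold"` thresholds a scaled sum of the factors plus a small
#' label noise at zero, and `"class-conditional-mean"` draws balanced class
#' labels first and shifts each signal group's mean by class.
#'
#' @param n_train,n_test numbers of training and test cases.
#' @param group_sizes integer vector of signal-group feature counts.
#' @param p_total total number of features (the remainder beyond the signal
#'   groups is independent noise).
#' @param loadings G x K matrix of factor loadings (rows = signal groups,
#'   columns = latent factors); defaults to the identity.
#' @param noise_sd idiosyncratic noise scale of the signal features.
#' @param label_rule `"factor-threshold"` or `"class-conditional-mean"`.
#' @param class_means 2 x G matrix of class-conditional group means (row 1
#'   for class `y = 1`, row 2 for class `y = 0`); only used by the
#'   `"class-conditional-mean"` rule.
#' @param label_noise_sd sd of the additive label noise of the
#'   `"factor-threshold"` rule.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_train = 200, n_test = 1000,
                            group_sizes = c(50, 50, 50), p_total = 2000,
                            loadings = NULL, noise_sd = 0.5,
                            label_rule = c("factor-threshold",
                                           "class-conditional-mean"),
                            class_means = NULL, label_noise_sd = 0.1) {
  label_rule <- match.arg(label_rule)
  G <- length(group_sizes)
  if (is.null(loadings)) loadings <- diag(G)
  loadings <- as.matrix(loadings)
  stopifnot(sum(group_sizes) <= p_total, noise_sd > 0,
            nrow(loadings) == G)
  if (label_rule == "class-conditional-mean") {
    if (is.null(class_means)) stop("'class_means' required for this rule")
    class_means <- as.matrix(class_means)
    stopifnot(nrow(class_means) == 2, ncol(class_means) == G)
  }
  structure(list(n_train = n_train, n_test = n_test,
                 group_sizes = as.integer(group_sizes),
                 p_total = as.integer(p_total), loadings = loadings,
                 noise_sd = noise_sd, label_rule = label_rule,
                 class_means = class_means,
                 label_noise_sd = label_noise_sd),
            class = "simulation_spec")
}

#' Preset: independent groups of strongly informative features
#'
#' Three independent signal groups of 50 features on 2000, each group
#' loading on its own latent factor with unit loading and idiosyncratic sd
#' 0.5 (within-group correlation 0.8); labels threshold the scaled factor
#' sum `(z1 + z2 + z3)/sqrt(3)` plus N(0, 0.1) noise at zero.  200 training
#' and 1000 test cases.
#'
#' @return A [simulation_spec()].
#' @export
scenario_independent_groups <- function() {
  simulation_spec(n_train = 200, n_test = 1000,
                  group_sizes = c(50, 50, 50), p_total = 2000,
                  loadings = diag(3), noise_sd = 0.5,
                  label_rule = "factor-threshold", label_noise_sd = 0.1)
}

#' Preset: correlated weakly differentiated groups
#'
#' Three signal groups of 200 features on 2000.  Groups 1 and 2 share a
#' factor (cross-group feature correlation 0.64; within-group 0.8) and are
#' only weakly mean-differentiated between classes (means -0.3/0.3 and
#' 0.3/-0.3); group 3 is strongly differentiated (1/-1).  Labels are
#' balanced coin flips drawn before the features.
#'
#' @return A [simulation_spec()].
#' @export
scenario_correlated_weak <- function() {
  simulation_spec(n_train = 200, n_test = 1000,
                  group_sizes = c(200, 200, 200), p_total = 2000,
                  loadings = rbind(c(1, 0, 0), c(0.8, 0.6, 0), c(0, 0, 1)),
                  noise_sd = 0.5,
                  label_rule = "class-conditional-mean",
                  class_means = rbind(c(-0.3, 0.3, 1), c(0.3, -0.3, -1)),
                  label_noise_sd = 0)
}

#' Preset: desk-scale variant of the independent-groups design
#'
#' Same generative process as [scenario_independent_groups()] at reduced
#' size: three signal groups of 10 features on 200 total, 200 training and
#' 1000 test cases.
#'
#' @return A [simulation_spec()].
#' @export
scenario_independent_groups_small <- function() {
  simulation_spec(n_train = 200, n_test = 1000,
                  group_sizes = c(10, 10, 10), p_total = 200,
                  loadings = diag(3), noise_sd = 0.5,
                  label_rule = "factor-threshold", label_noise_sd = 0.1)
}

## draw (x, y) for n cases under a spec
simulate_cases <- function(spec, n) {
  G <- length(spec$group_sizes)
  K <- ncol(spec$loadings)
  z <- matrix(rnorm(n * K), n, K)
  p_sig <- sum(spec$group_sizes)
  p_noise <- spec$p_total - p_sig
  x <- matrix(NA_real_, n, spec$p_total)

  if (spec$label_rule == "factor-threshold") {
    y <- as.integer(rowSums(z[, seq_len(G), drop = FALSE]) / sqrt(G) +
                      spec$label_noise_sd * rnorm(n) > 0)
  } else {
    y <- rbinom(n, 1L, 0.5)
  }

  start <- 1L
  for (g in seq_len(G)) {
    sz <- spec$group_sizes[g]
    common <- drop(z %*% spec$loadings[g, ])
    mu <- if (spec$label_rule == "class-conditional-mean") {
      ifelse(y == 1L, spec$class_means[1, g], spec$class_means[2, g])
    } else 0
    x[, start:(start + sz - 1L)] <- mu + common +
      spec$noise_sd * matrix(rnorm(n * sz), n, sz)
    start <- start + sz
  }
  if (p_noise > 0)
    x[, (p_sig + 1L):spec$p_total] <- matrix(rnorm(n * p_noise), n, p_noise)
  list(x = x, y = y, z = z)
}

simulate_common <- function(spec, seed) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(spec$group_sizes)
  tr <- simulate_cases(spec, spec$n_train)
  te <- simulate_cases(spec, spec$n_test)
  feature_names <- paste0("f", seq_len(spec$p_total))
  group <- c(rep(seq_len(G), spec$group_sizes),
             rep(0L, spec$p_total - sum(spec$group_sizes)))
  truth <- data.frame(feature = feature_names, group = group,
                      signal = group > 0L)
  structure(list(train = robit_dataset(tr$x, tr$y, feature_names),
                 test = robit_dataset(te$x, te$y, feature_names),
                 truth = truth, spec = spec,
                 train_factors = tr$z, test_factors = te$z),
            class = "sim_data")
}

#' Simulate the independent-groups design
#'
#' @param spec a [simulation_spec()] with the `"factor-threshold"` label
#'   rule (default: [scenario_independent_groups()]).
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return An object of class `sim_data` with `train` and `test`
#'   [robit_dataset()]s, a `truth` data frame of per-feature group labels,
#'   and the latent factor draws (`train_factors`, `test_factors`).
#' @export
simulate_independent_groups <- function(spec = scenario_independent_groups(),
                                        seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"),
            spec$label_rule == "factor-threshold")
  simulate_common(spec, seed)
}

#' Simulate the correlated weakly differentiated design
#'
#' @param spec a [simulation_spec()] with the `"class-conditional-mean"`
#'   label rule (default: [scenario_correlated_weak()]).
#' @inheritParams simulate_independent_groups
#' @return A `sim_data` object (see [simulate_independent_groups()]).
#' @export
simulate_correlated_weak <- function(spec = scenario_correlated_weak(),
                                     seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"),
            spec$label_rule == "class-conditional-mean")
  simulate_common(spec, seed)
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("sim_data: %d train / %d test cases, %d features (%d signal in %d groups)\n",
              x$train$n, x$test$n, x$spec$p_total,
              sum(x$truth$signal), length(x$spec$group_sizes)))
  invisible(x)
}
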