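test_that("update-set selection follows the order-statistic rule", {
  ## top-1 of 10 variances, intercept (column 1) always included
  expect_identical(select_update_set(1:10, 0.1), c(1L, 11L))
  expect_identical(select_update_set(1:10, 1.0), 1:11)
  ## ties broken by lower feature index
  expect_identical(select_update_set(rep(2, 10), 0.2), 1:3)
  ## selection depends only on the variances handed in
  lam <- c(5, 1, 4, 2, 3)
  expect_identical(select_update_set(lam, 0.4), select_update_set(lam, 0.4))
  expect_identical(select_update_set(lam, 0.4), c(1L, 2L, 4L))
})

test_that("leapfrog trajectory is symplectic, reversible, and has an R twin", {
  set.seed(21)
  d <- robit_dataset(matrix(rnorm(60), 12, 5), rbinom(12, 1, 0.5))
  cfg <- robit_config()
  u <- c(1L, 2L, 4L)
  lam <- c(100, exp(runif(2, -3, 0)))
  b <- rnorm(3, 0, 0.3)
  mom <- rnorm(3)
  xu <- d$X[, u]
  mf <- drop(d$X[, -u] %*% rnorm(3, 0, 0.1))

  ## zero step size: identity map
  t0 <- leapfrog_trajectory(b, mom, xu, mf, d$y, lam, cfg, 0, 10)
  expect_equal(t0$beta, b)
  expect_equal(t0$energy0, t0$energy1)

  ## energy error vanishes as the step size shrinks
  t1 <- leapfrog_trajectory(b, mom, xu, mf, d$y, lam, cfg, 1e-4, 10)
  expect_lt(abs(t1$energy1 + sum(t1$momentum^2) / 2 -
                  t1$energy0 - sum(mom^2) / 2), 1e-5)

  ## reversibility: negate the final momentum and integrate back
  tf <- leapfrog_trajectory(b, mom, xu, mf, d$y, lam, cfg, 0.05, 25)
  tb <- leapfrog_trajectory(tf$beta, -tf$momentum, xu, mf, d$y, lam, cfg,
                            0.05, 25)
  expect_equal(tb$beta, b, tolerance = 1e-8)
  expect_equal(-tb$momentum, mom, tolerance = 1e-8)

  ## compiled Cauchy path agrees with the plain-R integrator
  tr <- robithl:::leapfrog_r(b, mom, xu, mf, d$y, lam, cfg, 0.05, 25)
  expect_equal(tf$beta, tr$beta, tolerance = 1e-10)
  expect_equal(tf$momentum, tr$momentum, tolerance = 1e-10)
  expect_equal(tf$energy1, tr$energy1, tolerance = 1e-10)

  ## with a diagonal mass matrix too
  im <- c(0.5, 2, 1.3)
  tm <- leapfrog_trajectory(b, mom, xu, mf, d$y, lam, cfg, 0.05, 25,
                            inv_mass = im)
  tmr <- robithl:::leapfrog_r(b, mom, xu, mf, d$y, lam, cfg, 0.05, 25,
                              inv_mass = im)
  expect_equal(tm$beta, tmr$beta, tolerance = 1e-10)
  tmb <- leapfrog_trajectory(tm$beta, -tm$momentum, xu, mf, d$y, lam, cfg,
                             0.05, 25, inv_mass = im)
  expect_equal(tmb$beta, b, tolerance = 1e-8)
})

test_that("hmc update accepts the identity proposal and freezes beta_F", {
  set.seed(22)
  d <- robit_dataset(matrix(rnorm(60), 12, 5), rbinom(12, 1, 0.5))
  lam <- c(100, exp(runif(5, -3, 0)))
  b <- rnorm(6, 0, 0.3)
  u <- c(1L, 3L, 5L)
  out <- hmc_update(b, lam, u, d, step_size = 0, leapfrog_steps = 10)
  expect_true(out$accepted)
  expect_equal(out$beta, b)
  expect_equal(out$delta_h, 0)
  out2 <- hmc_update(b, lam, u, d, step_size = 0.1, leapfrog_steps = 20)
  expect_equal(out2$beta[-u], b[-u])  # frozen block untouched
})

test_that("the chain is deterministic given a seed and rejects bad input", {
  set.seed(1)
  d <- robit_dataset(matrix(rnorm(200), 20, 10), rbinom(20, 1, 0.5))
  s <- sampler_settings(n_iter = 200, seed = 7, leapfrog_steps = 10)
  c1 <- run_mcmc(d, settings = s)
  c2 <- run_mcmc(d, settings = s)
  expect_identical(c1$beta_draws, c2$beta_draws)
  expect_identical(c1$lambda_draws, c2$lambda_draws)
  expect_true(c1$accept_rate >= 0 && c1$accept_rate <= 1)
  expect_equal(nrow(c1$beta_draws), s$n_iter - s$n_burnin)

  d_one <- robit_dataset(matrix(rnorm(20), 10, 2), rep(1L, 10))
  expect_error(run_mcmc(d_one, settings = s), "class")
})

test_that("cache of the frozen linear predictor stays coherent", {
  ## drive the Gibbs scan by hand through the exported pieces and compare
  ## the incrementally maintained X_F beta_F with direct recomputation
  set.seed(23)
  d <- robit_dataset(matrix(rnorm(300), 30, 10), rbinom(30, 1, 0.5))
  cfg <- robit_config()
  beta <- numeric(11)
  m_full <- numeric(30)
  for (it in 1:40) {
    lam_f <- sample_lambda_given_beta(beta[-1], cfg)
    u <- select_update_set(lam_f, 0.3)
    lam <- c(100, lam_f)
    m_fixed <- m_full - drop(d$X[, u] %*% beta[u])
    direct <- drop(d$X[, -u, drop = FALSE] %*% beta[-u])
    expect_equal(m_fixed, direct, tolerance = 1e-10)
    st <- hmc_update(beta, lam, u, d, cfg, step_size = 0.1,
                     leapfrog_steps = 10, cached_xf_betaf = m_fixed)
    beta <- st$beta
    m_full <- m_fixed + drop(d$X[, u] %*% beta[u])
  }
})

test_that("a separated single feature gets the right coefficient sign", {
  ## inflated prior scale so the signal is easily picked up
  cfg <- robit_config(omega1 = 1)
  hits <- 0
  for (seed in 1:30) {
    set.seed(seed)
    x <- c(rnorm(15, -2, 0.3), rnorm(15, 2, 0.3))
    y <- rep(c(0L, 1L), each = 15)
    d <- robit_dataset(matrix(x, 30, 1), y)
    ch <- run_mcmc(d, cfg, sampler_settings(n_iter = 400, seed = seed,
                                            update_fraction = 1,
                                            leapfrog_steps = 20))
    hits <- hits + (mean(ch$beta_draws[, 2]) > 0)
  }
  expect_gte(hits, 30 * 0.99)
})

test_that("retained log-posterior passes a Geweke stationarity check", {
  set.seed(24)
  x <- matrix(rnorm(40 * 10), 40, 10)
  y <- rbinom(40, 1, plogis(x[, 1] - x[, 2]))
  if (length(unique(y)) < 2) y[1] <- 1L - y[1]
  d <- robit_dataset(x, y)
  ch <- run_mcmc(d, settings = sampler_settings(n_iter = 5000, seed = 11,
                                                leapfrog_steps = 20))
  expect_lt(abs(geweke_z(ch$log_post)), 3)
})

test_that("restricted and unrestricted chains agree in distribution", {
  set.seed(25)
  x <- matrix(rnorm(50 * 4), 50, 4)
  y <- rbinom(50, 1, plogis(1.5 * x[, 1]))
  if (length(unique(y)) < 2) y[1] <- 1L - y[1]
  d <- robit_dataset(x, y)
  ch_r <- run_mcmc(d, settings = sampler_settings(n_iter = 12000,
                                                  n_burnin = 2000,
                                                  update_fraction = 0.5,
                                                  leapfrog_steps = 20,
                                                  seed = 31))
  ch_u <- run_mcmc(d, settings = sampler_settings(n_iter = 12000,
                                                  n_burnin = 2000,
                                                  update_fraction = 1,
                                                  leapfrog_steps = 20,
                                                  seed = 32))
  thin <- seq(1, 10000, by = 25)
  ks <- suppressWarnings(ks.test(ch_r$beta_draws[thin, 2],
                                 ch_u$beta_draws[thin, 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("indicator-pattern frequencies match the exact posterior", {
  ## quadrature oracle (frozen in helper-oracles.R): exact pattern
  ## probabilities of the 2-feature correlated problem
  fx <- quadrature_fixture()
  ch <- run_mcmc(fx$data,
                 settings = sampler_settings(n_iter = 20000, n_burnin = 2000,
                                             update_fraction = 1,
                                             leapfrog_steps = 50, seed = 5,
                                             standardize = FALSE))
  a <- abs(ch$beta_draws[, -1])
  mx <- pmax(a[, 1], a[, 2])
  i1 <- a[, 1] > 0.1 * mx
  i2 <- a[, 2] > 0.1 * mx
  got <- c(mean(i1 & !i2), mean(!i1 & i2), mean(i1 & i2), mean(!i1 & !i2))
  expect_equal(got, unname(fx$exact), tolerance = 0.04)
})

test_that("perfectly correlated features split across posterior modes", {
  set.seed(26)
  x1 <- rnorm(80)
  y <- as.integer(x1 + 0.2 * rnorm(80) > 0)
  d <- robit_dataset(cbind(x1, x1), y)  # exact duplicates
  ch <- run_mcmc(d, settings = sampler_settings(n_iter = 8000,
                                                n_burnin = 1000,
                                                update_fraction = 1,
                                                leapfrog_steps = 50,
                                                seed = 13,
                                                standardize = FALSE))
  a <- abs(ch$beta_draws[, -1])
  mx <- pmax(a[, 1], a[, 2])
  lead1 <- a[, 1] > 0.1 * mx & a[, 2] <= 0.1 * mx
  lead2 <- a[, 2] > 0.1 * mx & a[, 1] <= 0.1 * mx
  both <- a[, 1] > 0.1 * mx & a[, 2] > 0.1 * mx
  ## both single-leader modes are visited, and exclusive leadership is the
  ## rule rather than the exception
  expect_gt(mean(lead1), 0.05)
  expect_gt(mean(lead2), 0.05)
  expect_gt(mean(lead1 | lead2), mean(both))
})

test_that("two-stage screening ranks by absolute posterior mean", {
  set.seed(27)
  sim <- simulate_independent_groups(
    simulation_spec(n_train = 120, n_test = 50, group_sizes = c(5, 5, 5),
                    p_total = 60), seed = 41)
  fit <- two_stage_fit(sim$train,
                       settings = sampler_settings(n_iter = 400, seed = 41,
                                                   leapfrog_steps = 20,
                                                   p_star = 20),
                       settings2 = sampler_settings(n_iter = 400, seed = 42,
                                                    leapfrog_steps = 20))
  ## ranking oracle: brute-force sort of the stage-1 posterior means
  oracle <- sort(order(abs(fit$stage1_means), decreasing = TRUE)[1:20])
  expect_identical(fit$selected, oracle)
  expect_identical(fit$chain$feature_names,
                   sim$train$feature_names[fit$selected])

  ## p <= p_star keeps the full feature set
  small <- robit_dataset(sim$train$X[, 2:7], sim$train$y)
  fit2 <- two_stage_fit(small,
                        settings = sampler_settings(n_iter = 200, seed = 43,
                                                    leapfrog_steps = 10,
                                                    p_star = 100),
                        settings2 = sampler_settings(n_iter = 200, seed = 44,
                                                     leapfrog_steps = 10))
  expect_identical(fit2$selected, 1:6)
})
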