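test_that("scaled-t CDF matches closed forms and a quadrature oracle", {
  expect_equal(student_t_cdf(0, 1, 0.5), 0.5)
  expect_equal(student_t_cdf(sqrt(0.5), 1, 0.5), 0.75)

  ## quadrature oracle: integrate the scaled-t density directly
  dens <- function(t) dt(t / sqrt(0.5), df = 1) / sqrt(0.5)
  q <- integrate(dens, -Inf, 3, rel.tol = 1e-12)$value
  expect_equal(student_t_cdf(3, 1, 0.5), q, tolerance = 1e-8)

  ## generic-alpha path agrees with the alpha = 1 closed form
  x <- seq(-100, 100, length.out = 401)
  expect_equal(0.5 + atan(x / sqrt(0.5)) / pi, pt(x / sqrt(0.5), df = 1),
               tolerance = 1e-10)
  expect_equal(student_t_cdf(1.3, 4, 2), pt(1.3 / sqrt(2), df = 4))

  expect_error(student_t_cdf(0, -1, 0.5), "alpha")
  expect_error(student_t_cdf(0, 1, 0), "omega")
})

test_that("t CDF is symmetric and the log-CDF is stable in deep tails", {
  x <- c(0, 0.3, 2, 50, 1e4)
  for (al in c(1, 3)) {
    expect_equal(student_t_cdf(-x, al, 0.5), 1 - student_t_cdf(x, al, 0.5),
                 tolerance = 1e-15)
  }
  ## log CDF: finite and correct far beyond where log(CDF) underflows
  lc <- student_t_log_cdf(c(-1e6, -1e3, 0, 1e3, 1e6), 1, 0.5)
  expect_true(all(is.finite(lc)))
  ## left tail of the Cauchy: T(x) ~ sqrt(omega)/(pi |x|)
  expect_equal(lc[1], log(sqrt(0.5) / (pi * 1e6)), tolerance = 1e-6)
  expect_equal(student_t_log_cdf(2, 1, 0.5), log(student_t_cdf(2, 1, 0.5)),
               tolerance = 1e-12)
})

test_that("log-likelihood matches closed forms and a summation oracle", {
  set.seed(11)
  d <- robit_dataset(matrix(rnorm(60), 12, 5), rbinom(12, 1, 0.5))
  cfg <- robit_config()

  expect_equal(log_likelihood(numeric(6), d, cfg), 12 * log(0.5))

  d1 <- robit_dataset(matrix(sqrt(0.5), 1, 1), 1L)
  expect_equal(log_likelihood(c(0, 1), d1, cfg), log(0.75),
               tolerance = 1e-12)

  ## term-by-term oracle with the plain CDF (safe at this scale)
  beta <- rnorm(6)
  m <- drop(d$X %*% beta)
  manual <- sum(ifelse(d$y == 1, log(student_t_cdf(m, 1, 0.5)),
                       log(1 - student_t_cdf(m, 1, 0.5))))
  expect_equal(log_likelihood(beta, d, cfg), manual, tolerance = 1e-8)

  ## permutation invariance over cases
  perm <- sample(12)
  dp <- robit_dataset(d$X[perm, -1], d$y[perm])
  expect_equal(log_likelihood(beta, dp, cfg), log_likelihood(beta, d, cfg))

  expect_error(log_likelihood(numeric(4), d, cfg), "length")
})

test_that("energy gradient matches central finite differences", {
  set.seed(42)
  cfg <- robit_config()
  worst <- 0
  for (rep in 1:100) {
    d <- robit_dataset(matrix(rnorm(200), 20, 10), rbinom(20, 1, 0.5))
    lam <- exp(runif(11, -6, 1))
    b <- rnorm(11, 0, 0.8)
    g <- neg_log_posterior_and_gradient(b, numeric(0), lam, d, cfg)$gradient
    fd <- vapply(1:11, function(j) {
      h <- 1e-6
      bp <- b; bp[j] <- bp[j] + h
      bm <- b; bm[j] <- bm[j] - h
      (neg_log_posterior_and_gradient(bp, numeric(0), lam, d, cfg)$energy -
         neg_log_posterior_and_gradient(bm, numeric(0), lam, d, cfg)$energy) /
        (2 * h)
    }, 0)
    worst <- max(worst, max(abs(fd - g) / pmax(abs(fd), 1e-8)))
  }
  expect_lt(worst, 1e-4)
})

test_that("energy decomposes into likelihood plus Gaussian prior terms", {
  set.seed(3)
  d <- robit_dataset(matrix(rnorm(80), 16, 5), rbinom(16, 1, 0.5))
  cfg <- robit_config()
  lam <- exp(runif(6, -4, 1))
  b <- rnorm(6, 0, 0.5)

  out <- neg_log_posterior_and_gradient(b, numeric(0), lam, d, cfg)
  expect_equal(out$energy,
               -log_likelihood(b, d, cfg) + sum(b^2 / (2 * lam)),
               tolerance = 1e-10)

  ## prior part of the gradient vanishes at beta = 0
  g0 <- neg_log_posterior_and_gradient(numeric(6), numeric(0), lam, d,
                                       cfg)$gradient
  gl <- neg_log_posterior_and_gradient(numeric(6), numeric(0), lam * 100,
                                       d, cfg)$gradient
  expect_equal(g0, gl)  # no lambda dependence left when beta_U = 0

  ## the cached frozen predictor is honoured, not recomputed
  u <- c(1L, 3L)
  f <- setdiff(1:6, u)
  cache <- drop(d$X[, f] %*% b[f])
  with_cache <- neg_log_posterior_and_gradient(b[u], b[f], lam[u], d, cfg,
                                               u = u, cached_xf_betaf = cache)
  fake <- neg_log_posterior_and_gradient(b[u], b[f], lam[u], d, cfg,
                                         u = u,
                                         cached_xf_betaf = cache + 1)
  expect_false(isTRUE(all.equal(with_cache$energy, fake$energy)))
  direct <- neg_log_posterior_and_gradient(b[u], b[f], lam[u], d, cfg, u = u)
  expect_equal(with_cache$energy, direct$energy, tolerance = 1e-12)

  expect_error(neg_log_posterior_and_gradient(b, numeric(0), -lam, d, cfg),
               "positive")
})

test_that("posterior-averaged prediction equals the explicit loop average", {
  set.seed(8)
  cfg <- robit_config()
  chain1 <- list(beta_draws = matrix(0, 1, 4))
  expect_equal(posterior_average_prediction(chain1, c(1, 1, 2, 3), cfg), 0.5)

  ## two draws engineered to give case probabilities 0.2 and 0.8
  x <- c(1, 1)
  b1 <- c(0, sqrt(0.5) * tan(pi * (0.2 - 0.5)))
  b2 <- c(0, sqrt(0.5) * tan(pi * (0.8 - 0.5)))
  chain2 <- list(beta_draws = rbind(b1, b2))
  expect_equal(posterior_average_prediction(chain2, x, cfg), 0.5,
               tolerance = 1e-12)

  B <- matrix(rnorm(50 * 6), 50, 6)
  xn <- rnorm(6)
  loop <- mean(vapply(1:50, function(i)
    student_t_cdf(sum(xn * B[i, ]), 1, 0.5), 0))
  expect_equal(posterior_average_prediction(list(beta_draws = B), xn, cfg),
               loop, tolerance = 1e-12)

  expect_error(posterior_average_prediction(list(beta_draws = NULL), xn, cfg),
               "draws")
})
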