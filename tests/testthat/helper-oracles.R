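## Shared independent oracles and small fixtures for the test suite.

## brute-force subset subdivision: one pass with a dictionary, no reuse of
## the package's indicator/filter/enumerate code paths
oracle_subsets <- function(beta_draws, rel_threshold = 0.1, min_freq = 0.05) {
  R <- nrow(beta_draws); p <- ncol(beta_draws)
  sel <- matrix(FALSE, R, p)
  for (i in seq_len(R)) {
    mx <- max(abs(beta_draws[i, ]))
    if (mx > 0) sel[i, ] <- abs(beta_draws[i, ]) > rel_threshold * mx
  }
  freq_j <- colSums(sel) / R
  sel[, freq_j < min_freq] <- FALSE
  keys <- apply(sel, 1, function(r) paste(which(r), collapse = ","))
  counts <- table(keys[keys != ""])
  out <- lapply(names(counts), function(k)
    list(members = as.integer(strsplit(k, ",")[[1]]),
         frequency = as.numeric(counts[[k]]) / R))
  out[order(vapply(out, function(s) -s$frequency, 0),
            vapply(out, function(s)
              paste(sprintf("%09d", s$members), collapse = ","), ""))]
}

## AUROC as the exhaustive concordant-pair fraction, ties counted 1/2
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
  conc / (length(pos) * length(neg))
}

## Geweke-style z-score with batch-means standard errors
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1L, n)]
  bm_var <- function(v) {
    nb <- max(5L, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    means <- vapply(seq_len(nb), function(k)
      mean(v[((k - 1) * bs + 1):(k * bs)]), 0)
    stats::var(means) / nb
  }
  (mean(a) - mean(b)) / sqrt(bm_var(a) + bm_var(b))
}

## the 2-correlated-feature dataset whose exact posterior indicator-pattern
## probabilities were computed by quadrature over (intercept, beta1, beta2)
## with the Cauchy(0, e^-5) prior (hybrid prior-quantile + linear grid,
## ~558 cells/dim, intercept ~ N(0, 100)); values frozen below
quadrature_fixture <- function() {
  set.seed(99)
  n <- 60
  z <- rnorm(n)
  x1 <- z + 0.5 * rnorm(n)
  x2 <- z + 0.5 * rnorm(n)
  y <- as.integer(z + 0.1 * rnorm(n) > 0)
  list(data = robit_dataset(cbind(x1, x2), y),
       ## P(pattern) for patterns (only f1), (only f2), (both), (none)
       exact = c(p10 = 0.9630, p01 = 0.0047, p11 = 0.0323, p00 = 0))
}

## tiny deterministic dataset used across evaluation tests; the first
## feature literally equals the label, the second is junk
toy_eval_data <- function() {
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  x <- cbind(as.numeric(y), c(0.3, -0.8, 1.1, -0.2, 0.7, -1.5))
  robit_dataset(x, y, c("s", "junk"))
}
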