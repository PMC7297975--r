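## Cauchy (hyper-LASSO) prior as a scale mixture of normals: latent-variance
## Gibbs conditional, inverse-gamma log-density, prior magnitude quantiles.

#' Gibbs draw of a latent prior variance given its coefficient
#'
#' The scaled-t coefficient prior is represented as a normal with a latent
#' per-coefficient variance `lambda_j`.  Conditional on `beta_j`, `lambda_j`
#' follows an Inverse-Gamma distribution with shape `(alpha1 + 1) / 2` and
#' rate `(alpha1 * omega1 + beta_j^2) / 2` (rate, not scale: the density is
#' proportional to `lambda^-(shape + 1) * exp(-rate / lambda)`).
#'
#' @param beta_j numeric vector of coefficient values; one variance is drawn
#'   per element.
#' @param cfg a [robit_config()].
#' @return Positive draws, one per element of `beta_j`.
#' @export
sample_lambda_given_beta <- function(beta_j, cfg = robit_config()) {
  shape <- (cfg$alpha1 + 1) / 2
  rate <- (cfg$alpha1 * cfg$omega1 + beta_j^2) / 2
  1 / rgamma(length(beta_j), shape = shape, rate = rate)
}

#' Log-density of the latent variance prior (up to a constant)
#'
#' The marginal prior on each latent variance is Inverse-Gamma with shape
#' `alpha1 / 2` and rate `alpha1 * omega1 / 2`; its log-density up to an
#' additive constant is `-(alpha1/2 + 1) log(lambda) - alpha1 omega1 / (2 lambda)`.
#'
#' @param lambda_j positive numeric vector.
#' @param cfg a [robit_config()].
#' @return Unnormalized log-densities (constant omitted).
#' @export
lambda_prior_logpdf <- function(lambda_j, cfg = robit_config()) {
  if (any(lambda_j <= 0)) stop("'lambda_j' must be positive")
  -(cfg$alpha1 / 2 + 1) * log(lambda_j) -
    cfg$alpha1 * cfg$omega1 / (2 * lambda_j)
}

## draw from the marginal lambda prior, Inverse-Gamma(alpha1/2, alpha1*omega1/2)
sample_lambda_prior <- function(n, cfg = robit_config()) {
  1 / rgamma(n, shape = cfg$alpha1 / 2, rate = cfg$alpha1 * cfg$omega1 / 2)
}

#' Upper-tail magnitude quantile of a centered Cauchy prior
#'
#' Returns the threshold `x` such that `P(|beta| >= x) = upper_prob` when
#' `beta ~ Cauchy(0, scale)`, i.e. `x = scale / tan(pi * upper_prob / 2)`.
#' Useful for reading off how many coefficients the prior expects to exceed
#' a given magnitude.
#'
#' @param upper_prob upper-tail probability in (0, 1].
#' @param scale Cauchy scale parameter (> 0).
#' @return A non-negative number (0 when `upper_prob` is 1).
#' @export
#' @examples
#' cauchy_magnitude_quantile(1e-4, exp(-5))  # ~= 42.895
cauchy_magnitude_quantile <- function(upper_prob, scale) {
  if (!is.numeric(upper_prob) || any(upper_prob <= 0) || any(upper_prob > 1))
    stop("'upper_prob' must lie in (0, 1]")
  if (!is.numeric(scale) || any(scale <= 0))
    stop("'scale' must be positive")
  ifelse(upper_prob == 1, 0, scale / tan(pi * upper_prob / 2))
}

## CDF of Inverse-Gamma(shape, rate), used by tests as a distributional target
pinvgamma <- function(q, shape, rate) {
  ifelse(q <= 0, 0, pgamma(1 / q, shape = shape, rate = rate,
                           lower.tail = FALSE))
}
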