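#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Stable log CDF of a standard Cauchy at u (scale already divided out).
// For u < 0 the exact identity T(u) = atan(-1/u)/pi keeps the log finite.
static inline double cauchy_log_cdf(double u) {
  if (u < 0.0)
    return std::log(std::atan(-1.0 / u)) - std::log(M_PI);
  if (u == 0.0)
    return std::log(0.5);
  return std::log1p(-std::atan(1.0 / u) / M_PI);
}

// Negative conditional log posterior of the active block (Cauchy link,
// alpha0 = 1) and its gradient.  m_fixed holds the cached X_F beta_F.
// Returns the energy; writes the gradient into grad.
static double energy_grad(const NumericMatrix &XU,
                          const NumericVector &m_fixed,
                          const IntegerVector &y,
                          const std::vector<double> &beta,
                          const NumericVector &lambda,
                          double omega0,
                          std::vector<double> &grad) {
  const int n = XU.nrow(), k = XU.ncol();
  const double s = std::sqrt(omega0);
  const double log_pis = std::log(M_PI * s);
  std::vector<double> w(n);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = m_fixed[i];
    for (int j = 0; j < k; ++j) m += XU(i, j) * beta[j];
    const double u = m / s;
    const double lt = -log_pis - std::log1p(u * u);
    if (y[i] == 1) {
      const double lT = cauchy_log_cdf(u);
      nll -= lT;
      w[i] = -std::exp(lt - lT);
    } else {
      const double lT = cauchy_log_cdf(-u);
      nll -= lT;
      w[i] = std::exp(lt - lT);
    }
  }
  double energy = nll;
  for (int j = 0; j < k; ++j) {
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += XU(i, j) * w[i];
    grad[j] = g + beta[j] / lambda[j];
    energy += beta[j] * beta[j] / (2.0 * lambda[j]);
  }
  return energy;
}

// One leapfrog trajectory of the HMC update for the active coefficient
// block under the Cauchy-link Robit posterior, with a diagonal mass matrix
// (inv_mass = 1/m_j; position step is eps * inv_mass_j * p_j).  Pure
// function: momenta are drawn by the caller, no RNG is used here.
// [[Rcpp::export]]
List cpp_leapfrog_cauchy(NumericMatrix XU, NumericVector m_fixed,
                         IntegerVector y, NumericVector beta0,
                         NumericVector p0, NumericVector lambda,
                         double omega0, double step_size, int n_steps,
                         NumericVector inv_mass) {
  const int k = XU.ncol();
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> grad(k);

  const double energy0 = energy_grad(XU, m_fixed, y, beta, lambda, omega0, grad);
  double energy1 = energy0;
  bool ok = std::isfinite(energy0);

  if (ok && step_size > 0.0 && n_steps > 0) {
    for (int j = 0; j < k; ++j) p[j] -= 0.5 * step_size * grad[j];
    for (int l = 0; l < n_steps; ++l) {
      for (int j = 0; j < k; ++j) beta[j] += step_size * inv_mass[j] * p[j];
      energy1 = energy_grad(XU, m_fixed, y, beta, lambda, omega0, grad);
      if (!std::isfinite(energy1)) { ok = false; break; }
      const double f = (l + 1 == n_steps) ? 0.5 : 1.0;
      for (int j = 0; j < k; ++j) p[j] -= f * step_size * grad[j];
    }
  }

  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["momentum"] = NumericVector(p.begin(), p.end()),
                      _["energy0"] = energy0,
                      _["energy1"] = energy1,
                      _["ok"] = ok);
}

// Energy and gradient exposed for cross-checking against the R implementation.
// [[Rcpp::export]]
List cpp_energy_grad_cauchy(NumericMatrix XU, NumericVector m_fixed,
                            IntegerVector y, NumericVector beta,
                            NumericVector lambda, double omega0) {
  const int k = XU.ncol();
  std::vector<double> b(beta.begin(), beta.end());
  std::vector<double> grad(k);
  const double e = energy_grad(XU, m_fixed, y, b, lambda, omega0, grad);
  return List::create(_["energy"] = e,
                      _["gradient"] = NumericVector(grad.begin(), grad.end()));
}
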