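// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Log marginal likelihood of a zero-mean Gaussian process with covariance
//   K(tau) = sigma2 * exp(-alpha * |tau|) * cos(beta * tau)
// observed with iid Gaussian technical noise of variance noise_var, plus a
// small relative jitter on the diagonal for numerical stability.
// beta = 0 gives the aperiodic OU kernel. Returns -1e10 when the Cholesky
// factorisation fails or parameters are invalid, so optimisers back away.
// [[Rcpp::export]]
double gp_loglik_cpp(const arma::vec& times, const arma::vec& y,
                     double sigma2, double alpha, double beta,
                     double noise_var, double jitter_rel = 1e-6) {
  const int n = times.n_elem;
  if (!(sigma2 > 0.0) || !(alpha > 0.0) || beta < 0.0 || noise_var < 0.0)
    return -1e10;

  arma::mat K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = sigma2 + noise_var + jitter_rel * sigma2;
    for (int j = 0; j < i; ++j) {
      const double tau = std::fabs(times[i] - times[j]);
      const double v = sigma2 * std::exp(-alpha * tau) * std::cos(beta * tau);
      K(i, j) = v;
      K(j, i) = v;
    }
  }

  arma::mat L;
  if (!arma::chol(L, K, "lower")) return -1e10;

  arma::vec z = arma::solve(arma::trimatl(L), y);
  const double quad = arma::dot(z, z);
  const double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  const double ll = -0.5 * quad - 0.5 * logdet - 0.5 * n * std::log(2.0 * M_PI);
  return std::isfinite(ll) ? ll : -1e10;
}
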