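#include <Rcpp.h>
using namespace Rcpp;

// Repressive Hill function 1 / (1 + (x / P0)^n).
inline double hillr(double x, double P0, double n) {
  return 1.0 / (1.0 + std::pow(x / P0, n));
}

// Euler-Maruyama integration of the delayed autorepression /
// lateral-inhibition model on a fixed cell lattice.
//
// The full trajectory is stored and delayed terms are read back from it;
// before t = 0 the history is constant and equal to the initial state.
// Noise follows the chemical Langevin construction: one Gaussian increment
// per species per step with variance (production + degradation) * dt.
// Negative excursions are clipped to zero and counted.
//
// `neighbours` holds one 0-based integer vector per cell; an empty vector
// means the cell receives no lateral-inhibition signal (H_LI = 1).
// Uses R's RNG so set.seed() in R gives bit-for-bit reproducibility.
// [[Rcpp::export]]
List simulate_cpp(NumericVector m0, NumericVector p0, List neighbours,
                  double alpha_m, double alpha_p, double mu_m, double mu_p,
                  double P0_auto, double n_auto, double P0_LI, double n_LI,
                  int tau_auto_steps, int tau_LI_steps, bool coupled,
                  double dt, int n_steps, bool noise_on) {
  const int nc = m0.size();
  NumericMatrix m(nc, n_steps + 1), p(nc, n_steps + 1);
  for (int c = 0; c < nc; ++c) {
    m(c, 0) = m0[c];
    p(c, 0) = p0[c];
  }

  std::vector<std::vector<int> > nbr(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = neighbours[c];
    nbr[c] = std::vector<int>(v.begin(), v.end());
  }

  long n_clipped = 0;
  const double sqdt = std::sqrt(dt);

  for (int k = 1; k <= n_steps; ++k) {
    const int prev = k - 1;
    const int ka = std::max(0, prev - tau_auto_steps);
    const int kl = std::max(0, prev - tau_LI_steps);

    for (int c = 0; c < nc; ++c) {
      const double mc = m(c, prev), pc = p(c, prev);

      double h_li = 1.0;
      if (coupled && !nbr[c].empty()) {
        double s = 0.0;
        for (size_t q = 0; q < nbr[c].size(); ++q) s += p(nbr[c][q], kl);
        h_li = hillr(s / nbr[c].size(), P0_LI, n_LI);
      }
      const double prod_m = alpha_m * hillr(p(c, ka), P0_auto, n_auto) * h_li;
      const double deg_m = mu_m * mc;
      const double prod_p = alpha_p * mc;
      const double deg_p = mu_p * pc;

      double dm = (prod_m - deg_m) * dt;
      double dp = (prod_p - deg_p) * dt;
      if (noise_on) {
        dm += std::sqrt(prod_m + deg_m) * sqdt * R::norm_rand();
        dp += std::sqrt(prod_p + deg_p) * sqdt * R::norm_rand();
      }

      double mn = mc + dm, pn = pc + dp;
      if (mn < 0.0) { mn = 0.0; ++n_clipped; }
      if (pn < 0.0) { pn = 0.0; ++n_clipped; }
      if (!std::isfinite(mn) || !std::isfinite(pn))
        stop("non-finite state at step %d (t = %.4f h)", k, k * dt);
      m(c, k) = mn;
      p(c, k) = pn;
    }
  }

  return List::create(_["m"] = m, _["p"] = p,
                      _["n_clipped"] = (double)n_clipped);
}
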