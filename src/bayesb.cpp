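#include <Rcpp.h>
using namespace Rcpp;

// BayesB single-site Gibbs sampler for whole-spectrum regression:
//   y_i = mu + sum_j x_ij beta_j + e_i,  e ~ N(0, ve)
// Each coefficient carries a point mass at zero with prior probability pi0
// and, when included, a normal slab whose variance has a scaled-inverse-
// chi-square prior (df nu, scale s0).  The indicator is sampled with beta_j
// integrated out (conjugate given the current slab variance), then beta_j is
// drawn from its full conditional.  Flat prior on mu and on ve.
// Uses R's RNG, so set.seed() in R governs the whole chain.
// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y, NumericMatrix X, double pi0, double nu,
                  double s0, int n_iter, int burn_in, int thin) {
  int n = y.size(), p = X.ncol();
  if (X.nrow() != n) stop("dim mismatch between y and X");
  std::vector<double> e(n), beta(p, 0.0), sig2(p, nu * s0 / (nu + 2.0));
  std::vector<int> delta(p, 0);
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = Rcpp::mean(y);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double ve = 0.0;
  for (int i = 0; i < n; ++i) ve += e[i] * e[i];
  ve = std::max(ve / n, 1e-12);

  int n_keep = (n_iter - burn_in) / thin;
  NumericVector ve_draws(n_keep), mu_draws(n_keep);
  std::vector<double> beta_sum(p, 0.0), incl_sum(p, 0.0);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept (flat prior)
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i];
    double mu_new = R::rnorm(mu + esum / n, std::sqrt(ve / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; delta[j] = 0; continue; }
      double bj = beta[j];
      // slab variance: full conditional when included, prior draw otherwise
      if (delta[j])
        sig2[j] = (nu * s0 + bj * bj) / R::rchisq(nu + 1.0);
      else
        sig2[j] = nu * s0 / R::rchisq(nu);
      // x_j' e with beta_j removed from the fit
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      xe += xtx[j] * bj;
      double lhs = xtx[j] / ve + 1.0 / sig2[j];
      double rhs = xe / ve;
      double logBF = 0.5 * rhs * rhs / lhs - 0.5 * std::log(sig2[j] * lhs);
      double p_in;
      if (pi0 <= 0.0) p_in = 1.0;
      else {
        double logodds = std::log((1.0 - pi0) / pi0) + logBF;
        p_in = 1.0 / (1.0 + std::exp(-logodds));
      }
      double bnew;
      if (R::unif_rand() < p_in) {
        bnew = R::rnorm(rhs / lhs, std::sqrt(1.0 / lhs));
        delta[j] = 1;
      } else {
        bnew = 0.0;
        delta[j] = 0;
      }
      double db = bnew - bj;
      if (db != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * db;
      beta[j] = bnew;
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = sse / R::rchisq(std::max(n - 2, 1));

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      ve_draws[kept] = ve;
      mu_draws[kept] = mu;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
      ++kept;
    }
  }
  if (kept == 0) stop("chain too short: no retained samples");
  NumericVector bmean(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = beta_sum[j] / kept;
    pip[j] = incl_sum[j] / kept;
  }
  double mu_mean = Rcpp::mean(mu_draws);
  return List::create(_["mu"] = mu_mean, _["beta"] = bmean,
                      _["pip"] = pip, _["ve_draws"] = ve_draws,
                      _["n_kept"] = kept);
}
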