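#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for the pedigree animal model
//   y = Xb + Z1 h + Z2 a + e
// with flat priors on b and on all variance components, herd/date effects
// h ~ N(0, vh I), additive effects a ~ N(0, va A) through the sparse A-inverse
// (compressed-column slots Ap/Ai/Ax over the full pedigree), and iid
// residuals.  Location effects are updated single-site (Gauss-Seidel order);
// variances from their scaled-inverse-chi-square (or inverse-Wishart) full
// conditionals.  All draws use R's RNG.

namespace {

struct RecIndex {
  std::vector<std::vector<int>> by_level;
  RecIndex(const IntegerVector &idx, int nlev, int n) : by_level(nlev) {
    for (int i = 0; i < n; ++i)
      if (idx[i] >= 0) by_level[idx[i]].push_back(i);
  }
};

// quadratic form a' Ainv b over the sparse symmetric Ainv
double quad_sparse(const IntegerVector &Ap, const IntegerVector &Ai,
                   const NumericVector &Ax, const double *a, const double *b) {
  double s = 0.0;
  int q = Ap.size() - 1;
  for (int col = 0; col < q; ++col)
    for (int k = Ap[col]; k < Ap[col + 1]; ++k)
      s += a[Ai[k]] * Ax[k] * b[col];
  return s;
}

// 2x2 inverse-Wishart draw: scale S (sums of squares), degrees of freedom df.
// W ~ Wishart(df, S^{-1}) via Bartlett, return W^{-1}.
void riwish2(const double S[3], double df, double out[3]) {
  // S stored as (s11, s12, s22); invert S
  double det = S[0] * S[2] - S[1] * S[1];
  if (det <= 0.0) stop("non-positive-definite scale matrix in inverse-Wishart");
  double V11 = S[2] / det, V12 = -S[1] / det, V22 = S[0] / det;
  // lower Cholesky of V
  double L11 = std::sqrt(V11), L21 = V12 / L11;
  double L22 = std::sqrt(V22 - L21 * L21);
  // Bartlett factor
  double Z11 = std::sqrt(R::rchisq(df));
  double Z21 = R::norm_rand();
  double Z22 = std::sqrt(R::rchisq(df - 1.0));
  // M = L Z (lower triangular), W = M M'
  double M11 = L11 * Z11;
  double M21 = L21 * Z11 + L22 * Z21;
  double M22 = L22 * Z22;
  double W11 = M11 * M11;
  double W12 = M11 * M21;
  double W22 = M21 * M21 + M22 * M22;
  double wdet = W11 * W22 - W12 * W12;
  out[0] = W22 / wdet; out[1] = -W12 / wdet; out[2] = W11 / wdet;
}

inline void inv2(const double M[3], double out[3]) {
  double det = M[0] * M[2] - M[1] * M[1];
  if (det <= 0.0) stop("singular 2x2 covariance matrix");
  out[0] = M[2] / det; out[1] = -M[1] / det; out[2] = M[0] / det;
}

} // namespace

// [[Rcpp::export]]
List animal_gibbs_uni(NumericVector y, NumericMatrix X, IntegerVector hidx,
                      int nh, IntegerVector aidx, IntegerVector Ap,
                      IntegerVector Ai, NumericVector Ax, int n_iter,
                      int burn_in, int thin) {
  int n = y.size(), p = X.ncol(), q = Ap.size() - 1;
  if (n < 5) stop("too few records");
  if (nh < 3 || q < 3) stop("need >= 3 herd levels and >= 3 pedigree animals");
  RecIndex herds(hidx, nh, n), anims(aidx, q, n);

  std::vector<double> b(p, 0.0), h(nh, 0.0), a(q, 0.0), e(y.begin(), y.end());
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double vy = Rcpp::var(y);
  if (vy <= 0.0) stop("response is constant: variance components unidentifiable");
  double va = 0.25 * vy, vh = 0.25 * vy, ve = 0.5 * vy;

  int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("chain too short for the requested burn-in/thinning");
  NumericVector va_d(n_keep), vh_d(n_keep), ve_d(n_keep);
  std::vector<double> a_sum(q, 0.0), b_sum(p, 0.0), h_sum(nh, 0.0);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      xe += xtx[j] * b[j];
      double lhs = xtx[j] / ve, rhs = xe / ve;
      double bnew = R::rnorm(rhs / lhs, std::sqrt(1.0 / lhs));
      double db = bnew - b[j];
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * db;
      b[j] = bnew;
    }
    // herd/date effects
    for (int k = 0; k < nh; ++k) {
      const std::vector<int> &rec = herds.by_level[k];
      double cnt = (double)rec.size(), se = 0.0;
      for (int r : rec) se += e[r];
      double lhs = cnt / ve + 1.0 / vh;
      double rhs = (se + cnt * h[k]) / ve;
      double hnew = R::rnorm(rhs / lhs, std::sqrt(1.0 / lhs));
      double dh = hnew - h[k];
      for (int r : rec) e[r] -= dh;
      h[k] = hnew;
    }
    // additive genetic effects
    for (int k = 0; k < q; ++k) {
      double Akk = 0.0, Asum = 0.0;
      for (int idx = Ap[k]; idx < Ap[k + 1]; ++idx) {
        int row = Ai[idx];
        if (row == k) Akk = Ax[idx];
        Asum += Ax[idx] * a[row];
      }
      const std::vector<int> &rec = anims.by_level[k];
      double cnt = (double)rec.size(), se = 0.0;
      for (int r : rec) se += e[r];
      double lhs = cnt / ve + Akk / va;
      double rhs = (se + cnt * a[k]) / ve - (Asum - Akk * a[k]) / va;
      double anew = R::rnorm(rhs / lhs, std::sqrt(1.0 / lhs));
      double da = anew - a[k];
      for (int r : rec) e[r] -= da;
      a[k] = anew;
    }
    // variance components (flat prior -> df = count - 2)
    double qa = quad_sparse(Ap, Ai, Ax, a.data(), a.data());
    va = std::max(qa / R::rchisq(std::max(q - 2, 1)), 1e-12);
    double sh = 0.0;
    for (int k = 0; k < nh; ++k) sh += h[k] * h[k];
    vh = std::max(sh / R::rchisq(std::max(nh - 2, 1)), 1e-12);
    double se2 = 0.0;
    for (int i = 0; i < n; ++i) se2 += e[i] * e[i];
    ve = std::max(se2 / R::rchisq(std::max(n - 2, 1)), 1e-12);

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      va_d[kept] = va; vh_d[kept] = vh; ve_d[kept] = ve;
      for (int k = 0; k < q; ++k) a_sum[k] += a[k];
      for (int k = 0; k < nh; ++k) h_sum[k] += h[k];
      for (int j = 0; j < p; ++j) b_sum[j] += b[j];
      ++kept;
    }
  }
  NumericVector am(q), hm(nh), bm(p);
  for (int k = 0; k < q; ++k) am[k] = a_sum[k] / kept;
  for (int k = 0; k < nh; ++k) hm[k] = h_sum[k] / kept;
  for (int j = 0; j < p; ++j) bm[j] = b_sum[j] / kept;
  return List::create(_["va"] = va_d, _["vh"] = vh_d, _["ve"] = ve_d,
                      _["b_mean"] = bm, _["h_mean"] = hm, _["a_mean"] = am);
}

// Bivariate version.  y is n x 2 and may contain NA; missing residuals are
// data-augmented each round from their conditional given the observed trait,
// so the complete-data inverse-Wishart full conditionals apply throughout.
// [[Rcpp::export]]
List animal_gibbs_biv(NumericMatrix y, NumericMatrix X, IntegerVector hidx,
                      int nh, IntegerVector aidx, IntegerVector Ap,
                      IntegerVector Ai, NumericVector Ax, int n_iter,
                      int burn_in, int thin) {
  int n = y.nrow(), p = X.ncol(), q = Ap.size() - 1;
  if (y.ncol() != 2) stop("bivariate sampler expects two trait columns");
  if (nh < 4 || q < 4) stop("need >= 4 herd levels and >= 4 pedigree animals");
  RecIndex herds(hidx, nh, n), anims(aidx, q, n);

  std::vector<double> b(2 * p, 0.0), h(2 * nh, 0.0), a(2 * q, 0.0);
  std::vector<double> e(2 * n, 0.0);
  std::vector<int> miss(2 * n, 0);
  double mu0[2] = {0.0, 0.0}, vy[2];
  for (int t = 0; t < 2; ++t) {
    double s = 0.0, ss = 0.0; int m = 0;
    for (int i = 0; i < n; ++i)
      if (!NumericMatrix::is_na(y(i, t))) { s += y(i, t); ++m; }
    if (m < 5) stop("too few observed records for one of the traits");
    mu0[t] = s / m;
    for (int i = 0; i < n; ++i)
      if (!NumericMatrix::is_na(y(i, t))) ss += (y(i, t) - mu0[t]) * (y(i, t) - mu0[t]);
    vy[t] = ss / (m - 1);
    if (vy[t] <= 0.0) stop("a response is constant");
    for (int i = 0; i < n; ++i) {
      if (NumericMatrix::is_na(y(i, t))) { miss[2 * i + t] = 1; e[2 * i + t] = 0.0; }
      else e[2 * i + t] = y(i, t) - mu0[t];
    }
  }
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  // start at diagonal partitions of the phenotypic variances
  double G0[3] = {0.25 * vy[0], 0.0, 0.25 * vy[1]};
  double H0[3] = {0.25 * vy[0], 0.0, 0.25 * vy[1]};
  double R0[3] = {0.5 * vy[0], 0.0, 0.5 * vy[1]};
  // recentre: put the observed means into the first fixed column (intercept)
  b[0] = mu0[0]; b[p] = mu0[1];

  int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("chain too short for the requested burn-in/thinning");
  NumericMatrix Gd(n_keep, 3), Hd(n_keep, 3), Rd(n_keep, 3);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double Rinv[3], Ginv[3], Hinv[3];
    // augment missing residuals from e_t | e_s
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < 2; ++t)
        if (miss[2 * i + t]) {
          int s = 1 - t;
          double rtt = t == 0 ? R0[0] : R0[2];
          double rss = t == 0 ? R0[2] : R0[0];
          double cm = R0[1] / rss * e[2 * i + s];
          double cv = rtt - R0[1] * R0[1] / rss;
          e[2 * i + t] = R::rnorm(cm, std::sqrt(std::max(cv, 1e-12)));
        }
    inv2(R0, Rinv); inv2(G0, Ginv); inv2(H0, Hinv);
    auto rtt = [&](int t) { return t == 0 ? Rinv[0] : Rinv[2]; };
    auto gtt = [&](int t) { return t == 0 ? Ginv[0] : Ginv[2]; };
    auto htt = [&](int t) { return t == 0 ? Hinv[0] : Hinv[2]; };

    // fixed effects
    for (int t = 0; t < 2; ++t)
      for (int j = 0; j < p; ++j) {
        if (xtx[j] <= 0.0) continue;
        double bj = b[t * p + j];
        double acc = 0.0;
        for (int i = 0; i < n; ++i) {
          double xij = X(i, j);
          if (xij == 0.0) continue;
          acc += xij * (rtt(t) * (e[2 * i + t] + xij * bj) +
                        Rinv[1] * e[2 * i + (1 - t)]);
        }
        double lhs = rtt(t) * xtx[j];
        double bnew = R::rnorm(acc / lhs, std::sqrt(1.0 / lhs));
        double db = bnew - bj;
        for (int i = 0; i < n; ++i) e[2 * i + t] -= X(i, j) * db;
        b[t * p + j] = bnew;
      }
    // herd/date effects
    for (int t = 0; t < 2; ++t)
      for (int k = 0; k < nh; ++k) {
        const std::vector<int> &rec = herds.by_level[k];
        double hk = h[t * nh + k], acc = 0.0;
        for (int r : rec)
          acc += rtt(t) * (e[2 * r + t] + hk) + Rinv[1] * e[2 * r + (1 - t)];
        acc -= Hinv[1] * h[(1 - t) * nh + k];
        double lhs = rtt(t) * rec.size() + htt(t);
        double hnew = R::rnorm(acc / lhs, std::sqrt(1.0 / lhs));
        double dh = hnew - hk;
        for (int r : rec) e[2 * r + t] -= dh;
        h[t * nh + k] = hnew;
      }
    // additive genetic effects
    for (int t = 0; t < 2; ++t)
      for (int k = 0; k < q; ++k) {
        double Akk = 0.0, Asum_t = 0.0, Asum_s = 0.0;
        for (int idx = Ap[k]; idx < Ap[k + 1]; ++idx) {
          int row = Ai[idx];
          if (row == k) Akk = Ax[idx];
          Asum_t += Ax[idx] * a[t * q + row];
          Asum_s += Ax[idx] * a[(1 - t) * q + row];
        }
        double ak = a[t * q + k];
        const std::vector<int> &rec = anims.by_level[k];
        double acc = 0.0;
        for (int r : rec)
          acc += rtt(t) * (e[2 * r + t] + ak) + Rinv[1] * e[2 * r + (1 - t)];
        acc -= gtt(t) * (Asum_t - Akk * ak) + Ginv[1] * Asum_s;
        double lhs = rtt(t) * rec.size() + gtt(t) * Akk;
        double anew = R::rnorm(acc / lhs, std::sqrt(1.0 / lhs));
        double da = anew - ak;
        for (int r : rec) e[2 * r + t] -= da;
        a[t * q + k] = anew;
      }
    // covariance matrices (flat priors -> minimal-df inverse-Wishart)
    double Sa[3] = {quad_sparse(Ap, Ai, Ax, &a[0], &a[0]),
                    quad_sparse(Ap, Ai, Ax, &a[0], &a[q]),
                    quad_sparse(Ap, Ai, Ax, &a[q], &a[q])};
    riwish2(Sa, (double)std::max(q - 3, 4), G0);
    double Sh[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < nh; ++k) {
      Sh[0] += h[k] * h[k];
      Sh[1] += h[k] * h[nh + k];
      Sh[2] += h[nh + k] * h[nh + k];
    }
    riwish2(Sh, (double)std::max(nh - 3, 4), H0);
    double Se[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < n; ++i) {
      Se[0] += e[2 * i] * e[2 * i];
      Se[1] += e[2 * i] * e[2 * i + 1];
      Se[2] += e[2 * i + 1] * e[2 * i + 1];
    }
    riwish2(Se, (double)std::max(n - 3, 4), R0);

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int c = 0; c < 3; ++c) {
        Gd(kept, c) = G0[c]; Hd(kept, c) = H0[c]; Rd(kept, c) = R0[c];
      }
      ++kept;
    }
  }
  return List::create(_["G"] = Gd, _["H"] = Hd, _["R"] = Rd);
}
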