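#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients for a sorted pedigree (parents before offspring).
// Parents are 0-based indices, -1 = unknown.  For each animal the row of the
// Cholesky path matrix is rebuilt sparsely over its ancestors, giving
// a_ii = sum_j v_j^2 D_j and F_i = a_ii - 1 (Meuwissen-Luo style recursion,
// O(ancestors) per animal instead of O(n^2) for the tabular method).
// [[Rcpp::export]]
NumericVector ped_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), v(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double fs = s >= 0 ? F[s] : -1.0;  // unknown parent contributes -1
    double fd = d >= 0 ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (s < 0 && d < 0) { F[i] = 0.0; continue; }
    double aii = 0.0;
    v[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      double vj = v[j];
      if (vj == 0.0) continue;
      aii += vj * vj * D[j];
      if (sire[j] >= 0) v[sire[j]] += 0.5 * vj;
      if (dam[j] >= 0) v[dam[j]] += 0.5 * vj;
      v[j] = 0.0;  // leave scratch clean for the next animal
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Triplets of A-inverse by Henderson's rules with inbreeding.
// Duplicated (i,j) entries are summed downstream when the triplet matrix is
// coerced to compressed column storage.
// [[Rcpp::export]]
List ainverse_triplets(IntegerVector sire, IntegerVector dam, NumericVector F) {
  int n = sire.size();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  ii.reserve(9 * n); jj.reserve(9 * n); xx.reserve(9 * n);
  auto add = [&](int a, int b, double val) {
    ii.push_back(a + 1); jj.push_back(b + 1); xx.push_back(val);
  };
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double fs = s >= 0 ? F[s] : -1.0;
    double fd = d >= 0 ? F[d] : -1.0;
    double m = 0.5 - 0.25 * (fs + fd);  // Mendelian sampling variance share
    double alpha = 1.0 / m;
    add(i, i, alpha);
    if (s >= 0) {
      add(i, s, -alpha / 2.0); add(s, i, -alpha / 2.0);
      add(s, s, alpha / 4.0);
    }
    if (d >= 0) {
      add(i, d, -alpha / 2.0); add(d, i, -alpha / 2.0);
      add(d, d, alpha / 4.0);
    }
    if (s >= 0 && d >= 0) {
      add(s, d, alpha / 4.0); add(d, s, alpha / 4.0);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}
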