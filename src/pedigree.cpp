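#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) recursion.
// `sire` and `dam` are 1-based indices into a parents-first ordering,
// 0 = unknown parent.  Returns F for every animal.
//
// For animal i the diagonal of the relationship matrix is
//   a_ii = sum_j L_ij^2 D_j,  F_i = a_ii - 1,
// where L_ij is accumulated by pushing 0.5 of each coefficient onto the
// parents, and D_j is the Mendelian-sampling variance of j given its
// parents' inbreeding (unknown parents treated as unrelated founders).
// [[Rcpp::export(name = ".inbreeding_cpp")]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> v(n + 1);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double fs = s > 0 ? F[s - 1] : 0.0;
    double fd = d > 0 ? F[d - 1] : 0.0;
    if (s > 0 && d > 0)       D[i] = 0.5  - 0.25 * (fs + fd);
    else if (s > 0 || d > 0)  D[i] = 0.75 - 0.25 * (s > 0 ? fs : fd);
    else                      D[i] = 1.0;

    if (s == 0 || d == 0) { F[i] = 0.0; continue; }

    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (v[j] == 0.0) continue;
      aii += v[j] * v[j] * D[j];
      if (sire[j] > 0) v[sire[j] - 1] += 0.5 * v[j];
      if (dam[j]  > 0) v[dam[j]  - 1] += 0.5 * v[j];
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Dense additive relationship matrix by the tabular method; indices as above.
// [[Rcpp::export(name = ".tabular_A_cpp")]]
NumericMatrix tabular_A_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s > 0) aij += 0.5 * A(j, s - 1);
      if (d > 0) aij += 0.5 * A(j, d - 1);
      A(i, j) = A(j, i) = aij;
    }
    double asd = (s > 0 && d > 0) ? A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
  }
  return A;
}
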