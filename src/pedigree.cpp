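#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) path-tracing scheme.
// sire/dam are 1-based internal ids, 0 = unknown; pedigree must be
// topologically ordered (parents before progeny).
// Unknown-parent convention: F = -1 inside d_i = 0.5 - 0.25 (F_s + F_d)
// yields d = 1 for founders and 0.75 - 0.25 F for one known parent.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n);
  std::vector<double> L(n);
  for (int i = 0; i < n; ++i) {
    double fs = (sire[i] > 0) ? F[sire[i] - 1] : -1.0;
    double fd = (dam[i] > 0) ? F[dam[i] - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (sire[i] == 0 && dam[i] == 0) { F[i] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * D[j];
      if (sire[j] > 0) L[sire[j] - 1] += 0.5 * lj;
      if (dam[j] > 0) L[dam[j] - 1] += 0.5 * lj;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// [[Rcpp::export]]
NumericMatrix build_A_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
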