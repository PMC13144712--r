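#include <Rcpp.h>
using namespace Rcpp;

// March the implicit soil-conduction recursion over a whole hourly series.
//
// The backward-Euler step for the interior nodes is
//   T_new = A %*% T_old + tb_new * avec
// where A = M^{-1}, M = I - dt * L (L the interior part of the discrete
// Laplacian) and avec = M^{-1} c carries the coupling of the first interior
// node to the prescribed surface boundary temperature.  A and avec are
// precomputed once in R; this kernel just runs the recursion, which dominates
// multi-decade, multi-pond runs.
//
// [[Rcpp::export]]
NumericMatrix soil_march_cpp(NumericMatrix A, NumericVector avec,
                             NumericVector tb, NumericVector t0) {
  const int m = t0.size();
  const int n = tb.size();
  if (A.nrow() != m || A.ncol() != m || avec.size() != m)
    stop("inconsistent dimensions in soil_march_cpp");
  NumericMatrix out(n, m);
  std::vector<double> cur(t0.begin(), t0.end());
  std::vector<double> nxt(m);
  for (int t = 0; t < n; ++t) {
    const double b = tb[t];
    for (int i = 0; i < m; ++i) {
      double s = avec[i] * b;
      for (int j = 0; j < m; ++j) s += A(i, j) * cur[j];
      nxt[i] = s;
    }
    for (int i = 0; i < m; ++i) {
      cur[i] = nxt[i];
      out(t, i) = nxt[i];
    }
  }
  return out;
}
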