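#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a symmetric positive-definite tridiagonal system.
// No pivoting: SPD guarantees stability. Solves one system per row of the
// inputs, so a full MM update for M sequences is a single call.

static void thomas_row(const double* d, const double* e, const double* b,
                       double* x, double* cp, double* dp, int n) {
  // d: diagonal (n), e: sub/super-diagonal (n-1), b: rhs (n)
  if (n == 1) {
    x[0] = b[0] / d[0];
    return;
  }
  cp[0] = e[0] / d[0];
  dp[0] = b[0] / d[0];
  for (int j = 1; j < n; ++j) {
    double denom = d[j] - e[j - 1] * cp[j - 1];
    if (j < n - 1) cp[j] = e[j] / denom;
    dp[j] = (b[j] - e[j - 1] * dp[j - 1]) / denom;
  }
  x[n - 1] = dp[n - 1];
  for (int j = n - 2; j >= 0; --j) x[j] = dp[j] - cp[j] * x[j + 1];
}

// [[Rcpp::export(name = ".thomas_solve_rows")]]
NumericMatrix thomas_solve_rows(NumericMatrix diag, NumericMatrix off,
                                NumericMatrix rhs) {
  int M = diag.nrow(), N = diag.ncol();
  if (rhs.nrow() != M || rhs.ncol() != N)
    stop("rhs dimensions must match diag");
  if (N > 1 && (off.nrow() != M || off.ncol() != N - 1))
    stop("off must be M x (N-1)");
  NumericMatrix x(M, N);
  std::vector<double> d(N), e(N > 1 ? N - 1 : 1), b(N), xr(N), cp(N), dp(N);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j) {
      d[j] = diag(i, j);
      b[j] = rhs(i, j);
      if (!R_finite(d[j]) || !R_finite(b[j]))
        stop("non-finite tridiagonal coefficient in row %d", i + 1);
    }
    for (int j = 0; j < N - 1; ++j) {
      e[j] = off(i, j);
      if (!R_finite(e[j]))
        stop("non-finite off-diagonal coefficient in row %d", i + 1);
    }
    thomas_row(d.data(), e.data(), b.data(), xr.data(), cp.data(), dp.data(), N);
    for (int j = 0; j < N; ++j) x(i, j) = xr[j];
  }
  return x;
}
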