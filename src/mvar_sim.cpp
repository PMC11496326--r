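#include <Rcpp.h>
using namespace Rcpp;

// Simulate x(t) = sum_k A(k) x(t-k) + e(t) given pre-drawn innovations.
// A is an n x n x p array (column-major), E is T x n; row t of the result
// is x(t)'.  The first p rows start from zero initial conditions; callers
// discard a burn-in long enough to wash those out.
// [[Rcpp::export]]
NumericMatrix var_simulate_cpp(NumericVector A, int n, int p, NumericMatrix E) {
  const int T = E.nrow();
  if (E.ncol() != n) stop("innovation matrix has wrong channel count");
  // work in channel-major (n x T) layout so each time step is contiguous
  std::vector<double> Yt((size_t)n * T, 0.0);
  const double* a = REAL(A);
  for (int t = 0; t < T; ++t) {
    double* yt = &Yt[(size_t)n * t];
    for (int i = 0; i < n; ++i) yt[i] = E(t, i);
    const int kmax = std::min(p, t);
    for (int k = 1; k <= kmax; ++k) {
      const double* Ak = a + (size_t)n * n * (k - 1);
      const double* ylag = &Yt[(size_t)n * (t - k)];
      for (int j = 0; j < n; ++j) {
        const double yj = ylag[j];
        const double* Acol = Ak + (size_t)n * j;
        for (int i = 0; i < n; ++i) yt[i] += Acol[i] * yj;
      }
    }
  }
  NumericMatrix Y(T, n);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i) Y(t, i) = Yt[(size_t)n * t + i];
  return Y;
}

// Cascade of second-order sections (direct form II transposed) with
// steady-state initial conditions scaled to the first sample, so step
// inputs produce no start-up transient.  sos rows: b0 b1 b2 a0 a1 a2
// with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  const R_xlen_t N = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    // steady-state state for unit step input
    const double K = (b0 + b1 + b2) / (1.0 + a1 + a2);
    const double z2i = b2 - a2 * K;
    const double z1i = b1 - a1 * K + z2i;
    double z1 = z1i * y[0], z2 = z2i * y[0];
    for (R_xlen_t t = 0; t < N; ++t) {
      const double xt = y[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt - a1 * yt + z2;
      z2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}
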