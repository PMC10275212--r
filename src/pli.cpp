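#include <Rcpp.h>
using namespace Rcpp;

// Mean sign of the instantaneous phase difference for every region pair of
// one epoch. X and Y hold the real and imaginary parts (samples x regions)
// of the analytic signals; Im(a_i * conj(a_j)) = Y_i X_j - X_i Y_j has the
// sign of the wrapped phase difference (0 at exact 0 / pi ties).
// [[Rcpp::export]]
NumericMatrix pli_epoch_cpp(NumericMatrix X, NumericMatrix Y) {
  const int T = X.nrow(), N = X.ncol();
  NumericMatrix out(N, N);
  for (int i = 0; i < N; ++i) {
    const double *xi = &X(0, i), *yi = &Y(0, i);
    for (int j = i + 1; j < N; ++j) {
      const double *xj = &X(0, j), *yj = &Y(0, j);
      long s = 0;
      for (int t = 0; t < T; ++t) {
        double v = yi[t] * xj[t] - xi[t] * yj[t];
        s += (v > 0.0) - (v < 0.0);
      }
      double p = std::fabs((double)s) / (double)T;
      out(i, j) = p;
      out(j, i) = p;
    }
  }
  return out;
}
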