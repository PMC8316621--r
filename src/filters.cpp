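#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads (second-order sections), direct form II transposed.
// sos: n_sections x 6 [b0 b1 b2 a0(=1) a1 a2]; zi: n_sections x 2 initial
// conditions (already scaled by the caller). Single forward pass.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const int T = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2),
      a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (int t = 0; t < T; ++t) {
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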