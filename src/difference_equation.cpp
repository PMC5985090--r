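#include <Rcpp.h>
using namespace Rcpp;

// Second-order IIR difference equation, direct form I, zero initial state:
//   a1*y[n] = b1*x[n] + b2*x[n-1] + b3*x[n-2] - a2*y[n-1] - a3*y[n-2]
// with x[k] = y[k] = 0 for k < 0. Coefficients arrive normalised (a1 = 1).
// [[Rcpp::export]]
NumericVector diff_eq_order2(NumericVector x, NumericVector b, NumericVector a) {
  if (b.size() != 3 || a.size() != 3)
    stop("coefficient triples of length 3 required");
  const R_xlen_t n = x.size();
  if (n < 1) stop("empty signal");
  NumericVector y(n);
  const double b1 = b[0], b2 = b[1], b3 = b[2];
  const double a1 = a[0], a2 = a[1], a3 = a[2];
  double xm1 = 0.0, xm2 = 0.0, ym1 = 0.0, ym2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = (b1 * xi + b2 * xm1 + b3 * xm2 - a2 * ym1 - a3 * ym2) / a1;
    y[i] = yi;
    xm2 = xm1; xm1 = xi;
    ym2 = ym1; ym1 = yi;
  }
  return y;
}
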