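#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y = filter(b, a, x).
// Coefficients are normalised by a[0]; state starts at zero, so callers
// wanting zero-phase behaviour must pad and run forward/backward themselves.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int order = std::max(nb, na) - 1;
  std::vector<double> bb(order + 1, 0.0), aa(order + 1, 0.0);
  double a0 = a[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nb; i++) bb[i] = b[i] / a0;
  for (int i = 0; i < na; i++) aa[i] = a[i] / a0;
  std::vector<double> z(order, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; i++) {
    double xi = x[i];
    double yi = bb[0] * xi + (order > 0 ? z[0] : 0.0);
    for (int j = 0; j < order - 1; j++)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (order > 0) z[order - 1] = bb[order] * xi - aa[order] * yi;
    y[i] = yi;
  }
  return y;
}
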