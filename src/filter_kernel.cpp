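#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// b, a are same-length coefficient vectors with a[0] == 1. zi has
// length(a) - 1 state entries (scaled by the caller). Returns the
// filtered signal; the final state is not needed by the zero-phase
// wrapper because padding absorbs it.
// [[Rcpp::export(name = ".df2t_filter")]]
NumericVector df2t_filter(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int m = b.size() - 1;  // filter order
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (m > 0)
      z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
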