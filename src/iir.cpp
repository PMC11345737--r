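#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. Coefficients are normalized by a[0]
// internally; state starts at zero (edge handling is done in R by padding).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int m = std::max(nb, na);
  std::vector<double> bn(m, 0.0), an(m, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) an[i] = a[i] / a0;
  std::vector<double> z(m - 1, 0.0);
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bn[0] * xt + (m > 1 ? z[0] : 0.0);
    for (int i = 0; i < m - 2; ++i)
      z[i] = bn[i + 1] * xt + z[i + 1] - an[i + 1] * yt;
    if (m > 1) z[m - 2] = bn[m - 1] * xt - an[m - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Lagged design matrix: X[t, (ch-1)*L + l] = data[ch, t + lag_l], zero padded,
// with a trailing all-ones intercept column.
// [[Rcpp::export]]
NumericMatrix lag_design_cpp(NumericMatrix data, IntegerVector lags) {
  const int n_ch = data.nrow(), n_s = data.ncol(), L = lags.size();
  NumericMatrix X(n_s, n_ch * L + 1);
  for (int ch = 0; ch < n_ch; ++ch) {
    for (int l = 0; l < L; ++l) {
      const int tau = lags[l];
      const int col = ch * L + l;
      const int t0 = std::max(0, -tau), t1 = std::min(n_s, n_s - tau);
      for (int t = t0; t < t1; ++t) X(t, col) = data(ch, t + tau);
    }
  }
  for (int t = 0; t < n_s; ++t) X(t, n_ch * L) = 1.0;
  return X;
}
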