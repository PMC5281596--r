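#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, single forward pass, in place.
// b and a must be padded to equal length with a[0] == 1.
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const size_t nz = b.size() - 1;
  std::vector<double> z(nz + 1, 0.0); // z[nz] is a permanent zero
  const double b0 = b[0];
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z[0];
    for (size_t j = 0; j < nz; ++j) z[j] = b[j + 1] * xi - a[j + 1] * yi + z[j + 1];
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering with reflective edge padding,
// applied independently to each column of x.
// [[Rcpp::export]]
NumericMatrix iir_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix x) {
  if (a.size() == 0 || a[0] == 0.0) stop("invalid denominator coefficients");
  const size_t ncoef = std::max(b.size(), a.size());
  std::vector<double> bv(ncoef, 0.0), av(ncoef, 0.0);
  for (R_xlen_t i = 0; i < b.size(); ++i) bv[i] = b[i] / a[0];
  for (R_xlen_t i = 0; i < a.size(); ++i) av[i] = a[i] / a[0];

  const int n = x.nrow(), nc = x.ncol();
  const int pad = 3 * (static_cast<int>(ncoef) - 1);
  if (n <= pad + 1) stop("signal too short for the requested filter order");

  NumericMatrix out(n, nc);
  std::vector<double> buf(n + 2 * pad);
  for (int c = 0; c < nc; ++c) {
    // odd reflection about the end points suppresses edge transients
    for (int i = 0; i < pad; ++i) buf[i] = 2.0 * x(0, c) - x(pad - i, c);
    for (int i = 0; i < n; ++i) buf[pad + i] = x(i, c);
    for (int i = 0; i < pad; ++i)
      buf[pad + n + i] = 2.0 * x(n - 1, c) - x(n - 2 - i, c);

    iir_pass(bv, av, buf);
    std::reverse(buf.begin(), buf.end());
    iir_pass(bv, av, buf);
    std::reverse(buf.begin(), buf.end());

    for (int i = 0; i < n; ++i) out(i, c) = buf[pad + i];
  }
  return out;
}
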