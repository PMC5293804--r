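#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1. The state is
// initialized to the DC steady state scaled by the first sample, so a
// constant series passes through unchanged (the usual filtfilt `zi`).
static void iir_filter(const std::vector<double>& b, const std::vector<double>& a,
                       std::vector<double>& x) {
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  if (!x.empty()) {
    double acc = 0.0;
    for (int i = nw - 1; i >= 1; --i) {
      double bi = (i < nb) ? b[i] : 0.0;
      double ai = (i < na) ? a[i] : 0.0;
      acc += bi - ai;
      w[i - 1] = acc * x[0];
    }
  }
  for (size_t i = 0; i < x.size(); ++i) {
    double xi = x[i];
    double yi = b[0] * xi + w[0];
    for (int k = 1; k < nw; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      w[k - 1] = bk * xi - ak * yi + ((k < nw - 1) ? w[k] : 0.0);
    }
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering with odd-symmetric edge
// extension, matching the usual filtfilt convention: the series is
// extended by `pad` mirrored samples at each end so filter transients
// die out outside the observation window.
// [[Rcpp::export(name = ".zero_phase_cpp")]]
NumericVector zero_phase_cpp(NumericVector x, NumericVector b, NumericVector a, int pad) {
  const int n = x.size();
  if (pad >= n) pad = n - 1;
  if (pad < 0) pad = 0;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  const int m = n + 2 * pad;
  std::vector<double> ext(m);
  for (int i = 0; i < pad; ++i)
    ext[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i)
    ext[pad + i] = x[i];
  for (int i = 0; i < pad; ++i)
    ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_filter(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());
  iir_filter(bb, aa, ext);
  std::reverse(ext.begin(), ext.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ext[pad + i];
  return out;
}

// Column-wise variant for filtering several series with one call.
// [[Rcpp::export(name = ".zero_phase_mat_cpp")]]
NumericMatrix zero_phase_mat_cpp(NumericMatrix x, NumericVector b, NumericVector a, int pad) {
  NumericMatrix out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j) {
    NumericVector col = x(_, j);
    out(_, j) = zero_phase_cpp(col, b, a, pad);
  }
  return out;
}
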