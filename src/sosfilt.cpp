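#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections applied forward along the rows of x
// (columns are independent series). sos has one section per row:
// b0 b1 b2 a0 a1 a2 with a0 == 1. The direct-form-II state of each section
// is initialised to its DC steady state for the first input sample, which
// suppresses start-up transients when the signal does not start at zero.
// [[Rcpp::export]]
NumericMatrix sos_filter_cpp(NumericMatrix x, NumericMatrix sos,
                             double gain) {
  int n = x.nrow(), m = x.ncol(), ns = sos.nrow();
  NumericMatrix y(clone(x));
  for (int j = 0; j < m; ++j) {
    double *col = &y(0, j);
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      const double denom = 1.0 + a1 + a2;
      double w_ss = (denom != 0.0 && n > 0) ? col[0] / denom : 0.0;
      double w1 = w_ss, w2 = w_ss;
      for (int i = 0; i < n; ++i) {
        const double w0 = col[i] - a1 * w1 - a2 * w2;
        col[i] = b0 * w0 + b1 * w1 + b2 * w2;
        w2 = w1;
        w1 = w0;
      }
    }
    for (int i = 0; i < n; ++i) col[i] *= gain;
  }
  return y;
}

// Centred FIR filtering of the columns of x with an odd-length kernel h;
// boundaries are zero-padded. Used by the polyphase resampler.
// [[Rcpp::export]]
NumericMatrix fir_filter_cpp(NumericMatrix x, NumericVector h) {
  int n = x.nrow(), m = x.ncol(), L = h.size();
  int half = (L - 1) / 2;
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    const double *col = &x(0, j);
    double *out = &y(0, j);
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const int kmin = std::max(0, i + half - (n - 1));
      const int kmax = std::min(L - 1, i + half);
      for (int k = kmin; k <= kmax; ++k) acc += h[k] * col[i + half - k];
      out[i] = acc;
    }
  }
  return y;
}
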