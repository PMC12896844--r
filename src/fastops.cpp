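// Hot inner kernels of the convolution engine: im2col gather, col2im
// scatter-add, and column-wise scale/shift (batch normalization). All
// indices are 1-based linear indices into the zero-padded tensor, as
// produced by the R caller.

#include <Rcpp.h>
using namespace Rcpp;

// Gather im2col columns from a padded tensor. idx0 holds the linear
// indices of the first kernel tap's window, ordered (pixel, channel)
// with hwn pixels per channel; offs holds the per-tap linear offsets.
// Output column layout: (tap - 1) * nc + channel.
// [[Rcpp::export]]
NumericMatrix im2col_gather(NumericVector xp, IntegerVector idx0,
                            IntegerVector offs, int hwn, int nc) {
  const int K = offs.size();
  NumericMatrix cols(no_init(hwn, K * nc));
  const double* x = xp.begin();
  for (int k = 0; k < K; ++k) {
    const int off = offs[k];
    for (int c = 0; c < nc; ++c) {
      const int* id = idx0.begin() + (R_xlen_t)c * hwn;
      double* dst = cols.begin() + ((R_xlen_t)(k * nc + c)) * hwn;
      for (int r = 0; r < hwn; ++r)
        dst[r] = x[(R_xlen_t)id[r] - 1 + off];
    }
  }
  return cols;
}

// Transpose of im2col_gather: scatter-add gradient columns back into a
// zero-initialized padded tensor of length np.
// [[Rcpp::export]]
NumericVector col2im_scatter(NumericMatrix gcols, IntegerVector idx0,
                             IntegerVector offs, double np) {
  const int K = offs.size();
  const int hwn = gcols.nrow();
  const int nc = gcols.ncol() / K;
  NumericVector gxp((R_xlen_t)np);
  double* g = gxp.begin();
  for (int k = 0; k < K; ++k) {
    const int off = offs[k];
    for (int c = 0; c < nc; ++c) {
      const int* id = idx0.begin() + (R_xlen_t)c * hwn;
      const double* src = gcols.begin() + ((R_xlen_t)(k * nc + c)) * hwn;
      for (int r = 0; r < hwn; ++r)
        g[(R_xlen_t)id[r] - 1 + off] += src[r];
    }
  }
  return gxp;
}

// y[r, c] = x[r, c] * a[c] + b[c]
// [[Rcpp::export]]
NumericMatrix colscale_shift(NumericMatrix x, NumericVector a,
                             NumericVector b) {
  const int nr = x.nrow(), ncol = x.ncol();
  NumericMatrix y(nr, ncol);
  for (int c = 0; c < ncol; ++c) {
    const double ac = a[c], bc = b[c];
    const double* src = x.begin() + (R_xlen_t)c * nr;
    double* dst = y.begin() + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) dst[r] = src[r] * ac + bc;
  }
  return y;
}

// y[r, c] = x[r, c] * a[c]
// [[Rcpp::export]]
NumericMatrix colscale(NumericMatrix x, NumericVector a) {
  const int nr = x.nrow(), ncol = x.ncol();
  NumericMatrix y(nr, ncol);
  for (int c = 0; c < ncol; ++c) {
    const double ac = a[c];
    const double* src = x.begin() + (R_xlen_t)c * nr;
    double* dst = y.begin() + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) dst[r] = src[r] * ac;
  }
  return y;
}
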