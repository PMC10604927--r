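#include <Rcpp.h>
using namespace Rcpp;

// im2col gather for 3x3 same-padding convolution.
// idx is (H*W) x 9 with 1-based source pixel indices, 0 = zero padding.
// Output layout: column j = (c-1)*9 + k (kernel offset fastest within each
// input channel), matching the weight-row order used by the R layers.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int HW = idx.nrow();
  const int C = X.ncol();
  NumericMatrix out(HW, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int k = 0; k < 9; ++k) {
      double* oc = &out(0, c * 9 + k);
      const int* ic = &idx(0, k);
      for (int p = 0; p < HW; ++p) {
        const int s = ic[p];
        oc[p] = s > 0 ? xc[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// in-place variant writing into a preallocated buffer, avoiding the
// allocation and garbage-collection churn of a fresh (HW x 9C) matrix per
// convolution call
// [[Rcpp::export]]
void im2col_fill(const NumericMatrix& X, const IntegerMatrix& idx,
                 NumericMatrix out) {
  const int HW = idx.nrow();
  const int C = X.ncol();
  if (out.nrow() != HW || out.ncol() != 9 * C)
    stop("im2col_fill: buffer has wrong shape");
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    for (int k = 0; k < 9; ++k) {
      double* oc = &out(0, c * 9 + k);
      const int* ic = &idx(0, k);
      for (int p = 0; p < HW; ++p) {
        const int s = ic[p];
        oc[p] = s > 0 ? xc[s - 1] : 0.0;
      }
    }
  }
}
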