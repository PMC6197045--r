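// Hot layer kernels for the 1-D training path. Only the memory-bound
// pieces live here (im2col gather, col2im scatter, pooling); the large
// matrix products stay in R where they hit BLAS directly.
//
// Layout contract (shared with R/cnn-layers.R): batched activations are
// arrays (H, B, D) — height fastest, then batch, then channel. The im2col
// matrix has rows ordered (i'' fast, then b) and columns (i' fast, then d),
// matching matrix(f, h * D, C) for a filter bank of dim (h, 1, D, C).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(const NumericVector& X, int H, int B, int D,
                           int h) {
  const int H2 = H - h + 1;
  NumericMatrix M(H2 * B, h * D);
  const double* x = X.begin();
  double* m = M.begin();
  for (int d = 0; d < D; ++d) {
    for (int ii = 0; ii < h; ++ii) {
      double* mcol = m + (std::size_t)(ii + d * h) * H2 * B;
      const double* xsl = x + (std::size_t)d * H * B;
      for (int b = 0; b < B; ++b) {
        std::memcpy(mcol + (std::size_t)b * H2,
                    xsl + (std::size_t)b * H + ii,
                    sizeof(double) * H2);
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_col2im1d(const NumericMatrix& dM, int H, int B, int D,
                           int h) {
  const int H2 = H - h + 1;
  NumericVector dX((std::size_t)H * B * D);
  const double* m = dM.begin();
  double* x = dX.begin();
  for (int d = 0; d < D; ++d) {
    for (int ii = 0; ii < h; ++ii) {
      const double* mcol = m + (std::size_t)(ii + d * h) * H2 * B;
      double* xsl = x + (std::size_t)d * H * B;
      for (int b = 0; b < B; ++b) {
        const double* src = mcol + (std::size_t)b * H2;
        double* dst = xsl + (std::size_t)b * H + ii;
        for (int i = 0; i < H2; ++i) dst[i] += src[i];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, B, D);
  return dX;
}

// [[Rcpp::export]]
List cpp_pool1d_fwd(const NumericVector& X, int H, int B, int D, int ph) {
  const int H2 = H / ph;
  NumericVector Y((std::size_t)H2 * B * D);
  IntegerVector win((std::size_t)H2 * B * D);
  const double* x = X.begin();
  double* y = Y.begin();
  int* w = win.begin();
  const std::size_t nbd = (std::size_t)B * D;
  for (std::size_t bd = 0; bd < nbd; ++bd) {
    const double* src = x + bd * H;
    double* yd = y + bd * H2;
    int* wd = w + bd * H2;
    for (int i = 0; i < H2; ++i) {
      const double* blk = src + (std::size_t)i * ph;
      double best = blk[0];
      int wi = 1;
      for (int p = 1; p < ph; ++p) {
        if (blk[p] > best) { best = blk[p]; wi = p + 1; }
      }
      yd[i] = best;
      wd[i] = wi;
    }
  }
  Y.attr("dim") = IntegerVector::create(H2, B, D);
  win.attr("dim") = IntegerVector::create(H2, B, D);
  return List::create(Named("Y") = Y, Named("win") = win);
}

// [[Rcpp::export]]
NumericVector cpp_pool1d_bwd(const NumericVector& dY,
                             const IntegerVector& win, int H, int B, int D,
                             int ph) {
  const int H2 = H / ph;
  NumericVector dX((std::size_t)H * B * D);
  const double* g = dY.begin();
  const int* w = win.begin();
  double* x = dX.begin();
  const std::size_t nbd = (std::size_t)B * D;
  for (std::size_t bd = 0; bd < nbd; ++bd) {
    const double* gd = g + bd * H2;
    const int* wd = w + bd * H2;
    double* dst = x + bd * H;
    for (int i = 0; i < H2; ++i) {
      dst[(std::size_t)i * ph + wd[i] - 1] = gd[i];
    }
  }
  dX.attr("dim") = IntegerVector::create(H, B, D);
  return dX;
}
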