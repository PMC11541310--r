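// Compiled kernels for the 3x3 "same" convolutions (zero padding 1).
// Each image is processed through a reused per-image im2col buffer
// (pixel-major: rows are (h, w) pixels, h fastest; columns are
// (offset, channel) taps, column (o-1)*C + c with o = (dh+2) + 3*(dw+1),
// taps at (h+dh, w+dw)), followed by a direct BLAS dgemm. Keeping the
// buffers per-image bounds the working set and avoids allocator churn.
// Array layout follows R: X[h,w,c,n] at h + H*(w + W*(c + C*n)), 0-based.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// fill the (HW x 9C) im2col buffer for image n
static void im2col_image(const double *x, double *buf, int H, int W, int C,
                         int n) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int dw = -1; dw <= 1; ++dw) {
    for (int dh = -1; dh <= 1; ++dh) {
      const int off = (dh + 1) + 3 * (dw + 1);
      const int h0 = dh < 0 ? 1 : 0;
      const int len = H - (dh != 0 ? 1 : 0);
      for (int c = 0; c < C; ++c) {
        double *dst0 = buf + ((R_xlen_t)off * C + c) * HW;
        const double *src0 = x + HW * (c + (R_xlen_t)C * n);
        for (int w = 0; w < W; ++w) {
          double *dst = dst0 + (R_xlen_t)H * w;
          const int ww = w + dw;
          if (ww < 0 || ww >= W) {
            std::memset(dst, 0, sizeof(double) * H);
            continue;
          }
          if (dh > 0) dst[H - 1] = 0.0;
          else if (dh < 0) dst[0] = 0.0;
          std::memcpy(dst + h0, src0 + (R_xlen_t)H * ww + h0 + dh,
                      sizeof(double) * len);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cs_conv3_fwd(NumericVector X, NumericMatrix Wm,
                           NumericVector b, int H, int W, int C, int N) {
  const int Cout = Wm.nrow();
  const int K = 9 * C;
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(HW * Cout * N);
  std::vector<double> col((size_t)HW * K);
  std::vector<double> y((size_t)HW * Cout);
  const double one = 1.0, zero = 0.0;
  const int m = (int)HW;
  const double *x = X.begin();
  double *o = out.begin();
  for (int n = 0; n < N; ++n) {
    im2col_image(x, col.data(), H, W, C, n);
    F77_CALL(dgemm)("N", "T", &m, &Cout, &K, &one, col.data(), &m,
                    Wm.begin(), &Cout, &zero, y.data(), &m FCONE FCONE);
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      const double *s = y.data() + (size_t)HW * c;
      double *d = o + HW * (c + (R_xlen_t)Cout * n);
      if (bc == 0.0) std::memcpy(d, s, sizeof(double) * HW);
      else for (R_xlen_t i = 0; i < HW; ++i) d[i] = s[i] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cs_conv3_bwd(NumericVector X, NumericVector dY, NumericMatrix Wm,
                  int H, int W, int C, int N) {
  const int Cout = Wm.nrow();
  const int K = 9 * C;
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector dX(HW * C * N);
  NumericMatrix dW(Cout, K);
  NumericVector db(Cout);
  std::vector<double> col((size_t)HW * K);
  std::vector<double> dyn((size_t)HW * Cout);
  std::vector<double> dcol((size_t)HW * K);
  const double one = 1.0, zero = 0.0;
  const int m = (int)HW;
  const double *x = X.begin();
  const double *dy = dY.begin();
  double *dx = dX.begin();
  for (int n = 0; n < N; ++n) {
    // pixel-major slice of dY for this image
    for (int c = 0; c < Cout; ++c) {
      const double *s = dy + HW * (c + (R_xlen_t)Cout * n);
      double *d = dyn.data() + (size_t)HW * c;
      std::memcpy(d, s, sizeof(double) * HW);
      double acc = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) acc += s[i];
      db[c] += acc;
    }
    im2col_image(x, col.data(), H, W, C, n);
    // dW += t(dyn) %*% col
    F77_CALL(dgemm)("T", "N", &Cout, &K, &m, &one, dyn.data(), &m,
                    col.data(), &m, &one, dW.begin(), &Cout FCONE FCONE);
    // dcol = dyn %*% Wm
    F77_CALL(dgemm)("N", "N", &m, &K, &Cout, &one, dyn.data(), &m,
                    Wm.begin(), &Cout, &zero, dcol.data(), &m FCONE FCONE);
    // col2im accumulate into dX image n
    for (int dw_ = -1; dw_ <= 1; ++dw_) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int off = (dh + 1) + 3 * (dw_ + 1);
        const int h0 = dh < 0 ? 1 : 0;
        const int len = H - (dh != 0 ? 1 : 0);
        for (int c = 0; c < C; ++c) {
          const double *src0 = dcol.data() + ((size_t)off * C + c) * HW;
          double *dst0 = dx + HW * (c + (R_xlen_t)C * n);
          for (int w = 0; w < W; ++w) {
            const int ww = w + dw_;
            if (ww < 0 || ww >= W) continue;
            const double *s = src0 + (R_xlen_t)H * w + h0;
            double *d = dst0 + (R_xlen_t)H * ww + h0 + dh;
            for (int i = 0; i < len; ++i) d[i] += s[i];
          }
        }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// pixel-major (H*W*N x C) matrix -> (H, W, C, N) array, with optional
// per-channel bias added on the way
// [[Rcpp::export]]
NumericVector cs_pixfirst_to_hwcn(NumericMatrix M, int H, int W, int N,
                                  Nullable<NumericVector> bias = R_NilValue) {
  const int C = M.ncol();
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(HW * C * N);
  const double *m = M.begin();
  double *x = out.begin();
  for (int c = 0; c < C; ++c) {
    const double b = bias.isNotNull() ? NumericVector(bias)[c] : 0.0;
    for (int n = 0; n < N; ++n) {
      const double *s = m + (R_xlen_t)c * HW * N + HW * n;
      double *d = x + HW * (c + (R_xlen_t)C * n);
      if (b == 0.0) std::memcpy(d, s, sizeof(double) * HW);
      else for (R_xlen_t i = 0; i < HW; ++i) d[i] = s[i] + b;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// (H, W, C, N) array -> pixel-major (H*W*N x C) matrix
// [[Rcpp::export]]
NumericMatrix cs_hwcn_to_pixfirst(NumericVector X, int H, int W, int C, int N) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericMatrix out(HW * N, C);
  const double *x = X.begin();
  double *m = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      std::memcpy(m + (R_xlen_t)c * HW * N + HW * n,
                  x + HW * (c + (R_xlen_t)C * n), sizeof(double) * HW);
  return out;
}
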