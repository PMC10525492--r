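// 3x3 / stride-1 / padding-1 convolution kernels used by the network
// engine. A channels-fastest tensor batch [C*H*W x N] is, in memory,
// exactly the C x (H*W*N) matrix of per-position channel vectors, so the
// convolution decomposes into nine BLAS dgemm products (one per kernel
// offset) followed by border-masked block adds -- no im2col patch
// matrices are ever materialized.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// run over valid output columns for offset (dh, dw): for each sample n and
// output column w, output rows h in [h0, h1) read source (h+dh-1, w+dw-1).
// fn(dst_col0, src_col0, len) receives contiguous column runs.
template <typename F>
static inline void offset_runs(int H, int W, int N, int dh, int dw, F fn) {
  const int sh = dh - 1, sw = dw - 1;       // source minus destination
  const int h0 = std::max(0, -sh), h1 = std::min(H, H - sh);
  if (h1 <= h0) return;
  const int w0 = std::max(0, -sw), w1 = std::min(W, W - sw);
  const int len = h1 - h0;
  for (int n = 0; n < N; ++n) {
    const int base = n * H * W;
    for (int w = w0; w < w1; ++w) {
      const int dst = base + w * H + h0;
      const int src = base + (w + sw) * H + h0 + sh;
      fn(dst, src, len);
    }
  }
}

// X [C*H*W x N], Wmat [K x C*9] (columns ordered c fastest, then dh, dw),
// b length K -> out [K*H*W x N]
// [[Rcpp::export]]
NumericMatrix cpp_conv3x3_fwd(const NumericMatrix& X, const NumericMatrix& Wmat,
                              const NumericVector& b, int C, int H, int W) {
  const int N = X.ncol();
  const int K = Wmat.nrow();
  const int HWN = H * W * N;
  NumericMatrix out(K * H * W, N);
  double* o = REAL(out);
  for (int q = 0; q < HWN; ++q)
    for (int k = 0; k < K; ++k) o[(R_xlen_t)q * K + k] = b[k];
  std::vector<double> tmp((size_t)K * HWN);
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  const double* x = REAL(const_cast<NumericMatrix&>(X));
  for (int dw = 0; dw < 3; ++dw) {
    for (int dh = 0; dh < 3; ++dh) {
      const double* Wo = &Wmat(0, C * (dh + 3 * dw));
      // tmp = Wo [K x C] * X [C x HWN]
      F77_CALL(dgemm)("N", "N", &K, &HWN, &C, &one, Wo, &K,
                      x, &C, &zero, tmp.data(), &K FCONE FCONE);
      offset_runs(H, W, N, dh, dw, [&](int dst, int src, int len) {
        const int m = K * len;
        F77_CALL(daxpy)(&m, &one, tmp.data() + (size_t)src * K, &ione,
                        o + (R_xlen_t)dst * K, &ione);
      });
    }
  }
  return out;
}

// gradients of cpp_conv3x3_fwd; returns dW [K x C*9], db [K], and
// (when want_dx) dX [C*H*W x N]
// [[Rcpp::export]]
List cpp_conv3x3_bwd(const NumericMatrix& X, const NumericMatrix& dOut,
                     const NumericMatrix& Wmat, int C, int H, int W,
                     bool want_dx) {
  const int N = X.ncol();
  const int K = Wmat.nrow();
  const int HWN = H * W * N;
  NumericMatrix dW(K, C * 9);
  NumericVector db(K);
  const double* do_ = REAL(const_cast<NumericMatrix&>(dOut));
  const double* x = REAL(const_cast<NumericMatrix&>(X));
  for (int q = 0; q < HWN; ++q)
    for (int k = 0; k < K; ++k) db[k] += do_[(R_xlen_t)q * K + k];
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  std::vector<double> shifted((size_t)C * HWN);
  std::vector<double> tmp;
  if (want_dx) tmp.resize((size_t)C * HWN);
  NumericMatrix dX(want_dx ? C * H * W : 1, want_dx ? N : 1);
  for (int dw = 0; dw < 3; ++dw) {
    for (int dh = 0; dh < 3; ++dh) {
      // shifted = X displaced by the offset, zero at borders
      std::memset(shifted.data(), 0, sizeof(double) * (size_t)C * HWN);
      offset_runs(H, W, N, dh, dw, [&](int dst, int src, int len) {
        std::memcpy(shifted.data() + (size_t)dst * C,
                    x + (R_xlen_t)src * C,
                    sizeof(double) * (size_t)C * len);
      });
      // dW_o [K x C] = dOut [K x HWN] * shifted' [HWN x C]
      F77_CALL(dgemm)("N", "T", &K, &C, &HWN, &one, do_, &K,
                      shifted.data(), &C, &zero,
                      &dW(0, C * (dh + 3 * dw)), &K FCONE FCONE);
      if (want_dx) {
        // tmp = Wo' [C x K] * dOut [K x HWN]; scatter back through offset
        const double* Wo = &Wmat(0, C * (dh + 3 * dw));
        F77_CALL(dgemm)("T", "N", &C, &HWN, &K, &one, Wo, &K, do_, &K,
                        &zero, tmp.data(), &C FCONE FCONE);
        double* dx = REAL(dX);
        offset_runs(H, W, N, dh, dw, [&](int dst, int src, int len) {
          const int m = C * len;
          F77_CALL(daxpy)(&m, &one, tmp.data() + (size_t)dst * C, &ione,
                          dx + (R_xlen_t)src * C, &ione);
        });
      }
    }
  }
  if (want_dx) return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
  return List::create(_["dW"] = dW, _["db"] = db);
}
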