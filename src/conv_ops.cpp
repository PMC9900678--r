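// Stride-1 2D convolution and max-pooling kernels for the reconstruction
// network. Activations are stored channel-major: a (C, H, W, N) tensor is a
// C x (H*W*N) column-major matrix whose column index is i + j*H + n*H*W.
// With zero padding applied in this layout, the shifted input needed for a
// kernel offset (di, dj) is the same matrix with its column pointer advanced
// by di + dj*Hp: every offset becomes one BLAS dgemm on a pointer-shifted
// view, with no gather copies. Columns that cross sample or row boundaries
// only ever land in padded output positions, which are discarded by the
// final valid-region gather.

#pragma GCC optimize("O3")
#pragma GCC target("avx2,fma")

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>

using namespace Rcpp;

static inline void dgemm_(const char *ta, const char *tb, int m, int n,
                          int k, double alpha, const double *a, int lda,
                          const double *b, int ldb, double beta, double *c,
                          int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c,
                  &ldc FCONE FCONE);
}

// Zero-pad (C, H, W, N) -> (C, H+2p, W+2p, N) in matrix form.
// [[Rcpp::export(name = ".cpp_pad")]]
NumericMatrix cpp_pad(NumericMatrix x, int H, int W, int N, int p) {
  const int C = x.nrow();
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericMatrix out(C, Hp * Wp * (R_xlen_t)N);
  const double *src = x.begin();
  double *dst = out.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j) {
      R_xlen_t scol = (R_xlen_t)n * H * W + (R_xlen_t)j * H;
      R_xlen_t dcol = (R_xlen_t)n * Hp * Wp + (R_xlen_t)(j + p) * Hp + p;
      std::memcpy(dst + dcol * C, src + scol * C,
                  sizeof(double) * (size_t)C * H);
    }
  return out;
}

// Strip padding: inverse of cpp_pad.
// [[Rcpp::export(name = ".cpp_unpad")]]
NumericMatrix cpp_unpad(NumericMatrix xp, int H, int W, int N, int p) {
  const int C = xp.nrow();
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericMatrix out(C, (R_xlen_t)H * W * N);
  const double *src = xp.begin();
  double *dst = out.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j) {
      R_xlen_t dcol = (R_xlen_t)n * H * W + (R_xlen_t)j * H;
      R_xlen_t scol = (R_xlen_t)n * Hp * Wp + (R_xlen_t)(j + p) * Hp + p;
      std::memcpy(dst + dcol * C, src + scol * C,
                  sizeof(double) * (size_t)C * H);
    }
  return out;
}

// Forward stride-1 convolution on a padded input. xp: (Cin, Hp*Wp*N);
// W: (Cout, Cin, kh, kw) flattened; returns (Cout, H*W*N) with H = Hp-kh+1.
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericMatrix cpp_conv_fwd(NumericMatrix xp, int Hp, int Wp, int N,
                           NumericVector Wt, IntegerVector wdims,
                           NumericVector bias) {
  const int Cout = wdims[0], Cin = wdims[1], kh = wdims[2], kw = wdims[3];
  const int H = Hp - kh + 1, W = Wp - kw + 1;
  const R_xlen_t Mp = (R_xlen_t)Hp * Wp * N;
  std::vector<double> yfull((size_t)Cout * Mp, 0.0);
  std::vector<double> wk((size_t)Cout * Cin);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          wk[co + (size_t)Cout * ci] =
            Wt[co + (R_xlen_t)Cout * ci +
               (R_xlen_t)Cout * Cin * (ki + kh * kj)];
      const R_xlen_t off = ki + (R_xlen_t)kj * Hp;
      dgemm_("N", "N", Cout, (int)(Mp - off), Cin, 1.0, wk.data(), Cout,
             xp.begin() + off * Cin, Cin, 1.0, yfull.data(), Cout);
    }
  NumericMatrix out(Cout, (R_xlen_t)H * W * N);
  double *dst = out.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j) {
      R_xlen_t dcol = (R_xlen_t)n * H * W + (R_xlen_t)j * H;
      R_xlen_t scol = (R_xlen_t)n * Hp * Wp + (R_xlen_t)j * Hp;
      std::memcpy(dst + dcol * Cout, yfull.data() + scol * Cout,
                  sizeof(double) * (size_t)Cout * H);
    }
  for (R_xlen_t c = 0; c < (R_xlen_t)H * W * N; ++c)
    for (int co = 0; co < Cout; ++co) dst[c * Cout + co] += bias[co];
  return out;
}

// Backward stride-1 convolution. Returns list(dxp, dW, db).
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericMatrix xp, NumericMatrix dy, int Hp, int Wp, int N,
                  NumericVector Wt, IntegerVector wdims) {
  const int Cout = wdims[0], Cin = wdims[1], kh = wdims[2], kw = wdims[3];
  const int H = Hp - kh + 1, W = Wp - kw + 1;
  const R_xlen_t Mp = (R_xlen_t)Hp * Wp * N;
  // scatter dy into padded-position layout
  std::vector<double> dyfull((size_t)Cout * Mp, 0.0);
  const double *src = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < W; ++j) {
      R_xlen_t scol = (R_xlen_t)n * H * W + (R_xlen_t)j * H;
      R_xlen_t dcol = (R_xlen_t)n * Hp * Wp + (R_xlen_t)j * Hp;
      std::memcpy(dyfull.data() + dcol * Cout, src + scol * Cout,
                  sizeof(double) * (size_t)Cout * H);
    }
  NumericVector dW((R_xlen_t)Cout * Cin * kh * kw);
  NumericVector db(Cout);
  NumericMatrix dxp(Cin, Mp);
  std::vector<double> wk((size_t)Cout * Cin);
  std::vector<double> dwk((size_t)Cout * Cin);
  for (R_xlen_t c = 0; c < (R_xlen_t)H * W * N; ++c)
    for (int co = 0; co < Cout; ++co) db[co] += src[c * Cout + co];
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      const R_xlen_t off = ki + (R_xlen_t)kj * Hp;
      const int Mv = (int)(Mp - off);
      // dW_k = dyfull[:, 0:Mv] * xp[:, off:off+Mv]^T
      dgemm_("N", "T", Cout, Cin, Mv, 1.0, dyfull.data(), Cout,
             xp.begin() + off * Cin, Cin, 0.0, dwk.data(), Cout);
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co) {
          wk[co + (size_t)Cout * ci] =
            Wt[co + (R_xlen_t)Cout * ci +
               (R_xlen_t)Cout * Cin * (ki + kh * kj)];
          dW[co + (R_xlen_t)Cout * ci +
             (R_xlen_t)Cout * Cin * (ki + kh * kj)] =
            dwk[co + (size_t)Cout * ci];
        }
      // dxp[:, off:] += W_k^T * dyfull[:, 0:Mv]
      dgemm_("T", "N", Cin, Mv, Cout, 1.0, wk.data(), Cout, dyfull.data(),
             Cout, 1.0, dxp.begin() + off * Cin, Cin);
    }
  return List::create(_["dxp"] = dxp, _["dW"] = dW, _["db"] = db);
}
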