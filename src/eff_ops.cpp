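// Fused kernels for the efficient module (parallel 1x1 / 3x3 / 5x5 /
// pool+1x1 branches over a shared input) and for batch-norm + ReLU.
//
// The efficient module is the bandwidth-critical part of the network: its
// input can be several hundred channels wide, and evaluating the branches
// separately would stream that input many times. The fused kernels tile by
// blocks of samples (each block's padded input stays cache-resident while
// all kernel offsets are applied), stack the branch weights so each offset
// costs exactly one BLAS dgemm, and write into caller-provided buffers so a
// training loop allocates its large activations once.

#pragma GCC optimize("O3")
#pragma GCC target("avx2,fma")

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const int NB = 8;  // samples per tile block

static inline void dgemm_(const char *ta, const char *tb, int m, int n,
                          int k, double alpha, const double *a, int lda,
                          const double *b, int ldb, double beta, double *c,
                          int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c,
                  &ldc FCONE FCONE);
}

// Offset groups for the expanded-GEMM formulation: the conv branches are
// one big weight matrix Wexp (w1 + 9*w2 + 25*w3 rows x Cin). A single GEMM
// E = Wexp * xp evaluates every branch at every offset in one sweep of the
// input; a cheap shift-add over row groups then reduces E to the output.
// The backward pass is the exact adjoint: scatter dy into the expanded row
// layout (D), then dW = D * xp' and dx = Wexp' * D, again one GEMM each.
struct OffGroup {
  R_xlen_t off;   // column shift di + dj*Hp
  int outRow;     // first row in the output (concat) layout
  int eRow;       // first row in the expanded layout
  int w;          // branch width
  int branch;     // 0 = 1x1, 1 = 3x3, 2 = 5x5
  int kidx;       // kernel-position index within the branch
};

static std::vector<OffGroup> make_groups(int w1, int w2, int w3, int Hp) {
  std::vector<OffGroup> g;
  if (w1) g.push_back({2 + (R_xlen_t)2 * Hp, 0, 0, w1, 0, 0});
  if (w2)
    for (int dj = 1; dj <= 3; ++dj)
      for (int di = 1; di <= 3; ++di) {
        const int k3 = (di - 1) + 3 * (dj - 1);
        g.push_back({di + (R_xlen_t)dj * Hp, w1, w1 + k3 * w2, w2, 1, k3});
      }
  if (w3)
    for (int dj = 0; dj < 5; ++dj)
      for (int di = 0; di < 5; ++di) {
        const int k5 = di + 5 * dj;
        g.push_back({di + (R_xlen_t)dj * Hp, w1 + w2, w1 + 9 * w2 + k5 * w3,
                     w3, 2, k5});
      }
  return g;
}

// Build Wexp (Rtot x Cin) from the branch weight arrays.
static std::vector<double> make_wexp(const std::vector<OffGroup> &groups,
                                     int Rtot, int Cin, const double *W1,
                                     const double *W3, const double *W5) {
  std::vector<double> wexp((size_t)Rtot * Cin);
  for (const auto &g : groups) {
    const double *src = g.branch == 0 ? W1 : (g.branch == 1 ? W3 : W5);
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < g.w; ++co)
        wexp[g.eRow + co + (size_t)Rtot * ci] =
          src[co + (R_xlen_t)g.w * ci + (R_xlen_t)g.w * Cin * g.kidx];
  }
  return wexp;
}

// Per-offset stacked weight matrices (shift-GEMM formulation, used when the
// input is narrow and the per-offset GEMM output is the wide side).
// Offsets are indexed di + 5*dj over the 5x5 window (pad 2). Row layout of
// the stacked output is [b1 (1x1) | b2 (3x3) | b3 (5x5)]; the per-offset
// GEMM covers the contiguous row range of the branches active at that
// offset:
//   center (2,2):        rows 0 .. w1+w2+w3   (all three)
//   central 3x3 others:  rows w1 .. w1+w2+w3  (b2, b3)
//   outer ring:          rows w1+w2 .. +w3    (b3 only)
struct StackedW {
  int w1, w2, w3, Cin;
  std::vector<double> wk[25];
  int row0[25], nrow[25];
  void build(const double *W1, const double *W3, const double *W5) {
    for (int dj = 0; dj < 5; ++dj)
      for (int di = 0; di < 5; ++di) {
        const int o = di + 5 * dj;
        const bool mid = di >= 1 && di <= 3 && dj >= 1 && dj <= 3;
        const bool ctr = di == 2 && dj == 2;
        row0[o] = ctr ? 0 : (mid ? w1 : w1 + w2);
        nrow[o] = (ctr ? w1 : 0) + (mid ? w2 : 0) + w3;
        wk[o].assign((size_t)nrow[o] * Cin, 0.0);
        double *dst = wk[o].data();
        int at = 0;
        if (ctr)  // 1x1 weights
          for (int ci = 0; ci < Cin; ++ci)
            for (int co = 0; co < w1; ++co)
              dst[at + co + (size_t)nrow[o] * ci] = W1[co + (R_xlen_t)w1 * ci];
        if (ctr) at += w1;
        if (mid) {  // 3x3 weight slice (di-1, dj-1)
          const int k3 = (di - 1) + 3 * (dj - 1);
          for (int ci = 0; ci < Cin; ++ci)
            for (int co = 0; co < w2; ++co)
              dst[at + co + (size_t)nrow[o] * ci] =
                W3[co + (R_xlen_t)w2 * ci + (R_xlen_t)w2 * Cin * k3];
          at += w2;
        }
        const int k5 = di + 5 * dj;
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < w3; ++co)
            dst[at + co + (size_t)nrow[o] * ci] =
              W5[co + (R_xlen_t)w3 * ci + (R_xlen_t)w3 * Cin * k5];
      }
  }
};

// Build the padded block tile (Cin x Hp*Wp*nb, pad 2) from the two input
// channel blocks (a concatenation that is never materialized in R).
static void build_tile(std::vector<double> &xp, const double *x1, int C1,
                       const double *x2, int C2, int H, int W, int n0,
                       int nb) {
  const int Cin = C1 + C2, Hp = H + 4, Wp = W + 4;
  std::fill(xp.begin(), xp.begin() + (size_t)Cin * Hp * Wp * nb, 0.0);
  for (int s = 0; s < nb; ++s)
    for (int j = 0; j < W; ++j) {
      R_xlen_t scol = (R_xlen_t)(n0 + s) * H * W + (R_xlen_t)j * H;
      R_xlen_t dcol = (R_xlen_t)s * Hp * Wp + (R_xlen_t)(j + 2) * Hp + 2;
      for (int i = 0; i < H; ++i) {
        double *d = xp.data() + (dcol + i) * Cin;
        std::memcpy(d, x1 + (scol + i) * C1, sizeof(double) * C1);
        if (C2)
          std::memcpy(d + C1, x2 + (scol + i) * C2, sizeof(double) * C2);
      }
    }
}

// [[Rcpp::export(name = ".cpp_eff_fwd")]]
RObject cpp_eff_fwd(NumericMatrix x1, NumericMatrix x2, int H, int W, int N,
                    NumericVector W1, NumericVector W3, NumericVector W5,
                    NumericVector Wp, IntegerVector widths,
                    NumericVector bias, NumericMatrix y,
                    IntegerMatrix best) {
  const int C1 = x1.nrow(), C2 = x2.nrow();
  const int Cin = C1 + C2;
  const int w1 = widths[0], w2 = widths[1], w3 = widths[2], w4 = widths[3];
  const int Wtot = w1 + w2 + w3 + w4, Wc = w1 + w2 + w3;
  const int Hp = H + 4, Wp_ = W + 4, tileP = Hp * Wp_;

  const bool use_expand = Cin >= 64;
  const auto groups = make_groups(w1, w2, w3, Hp);
  const int Rtot = w1 + 9 * w2 + 25 * w3;
  std::vector<double> wexp;
  StackedW sw{w1, w2, w3, Cin};
  if (use_expand)
    wexp = make_wexp(groups, Rtot, Cin, W1.begin(), W3.begin(), W5.begin());
  else
    sw.build(W1.begin(), W3.begin(), W5.begin());
  std::vector<double> pw((size_t)w4 * Cin);  // pool-branch 1x1 weights
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < w4; ++co)
      pw[co + (size_t)w4 * ci] = Wp[co + (R_xlen_t)w4 * ci];

  std::vector<double> xp((size_t)Cin * tileP * NB);
  std::vector<double> opad((size_t)Wc * tileP * NB);
  std::vector<double> E(use_expand ? (size_t)Rtot * tileP * NB : 0);
  std::vector<double> ptile((size_t)Cin * H * W * NB);
  std::vector<double> ptmp((size_t)w4 * H * W * NB);

  for (int n0 = 0; n0 < N; n0 += NB) {
    const int nb = std::min(NB, N - n0);
    const R_xlen_t tp = (R_xlen_t)tileP * nb;
    build_tile(xp, x1.begin(), C1, C2 ? x2.begin() : nullptr, C2, H, W, n0,
               nb);
    std::fill(opad.begin(), opad.begin() + (size_t)Wc * tp, 0.0);
    if (use_expand) {
      dgemm_("N", "N", Rtot, (int)tp, Cin, 1.0, wexp.data(), Rtot,
             xp.data(), Cin, 0.0, E.data(), Rtot);
      for (const auto &g : groups) {
        const R_xlen_t nc = tp - g.off;
        for (R_xlen_t c = 0; c < nc; ++c) {
          const double *src = E.data() + (c + g.off) * Rtot + g.eRow;
          double *dst = opad.data() + c * Wc + g.outRow;
          for (int r = 0; r < g.w; ++r) dst[r] += src[r];
        }
      }
    } else
    for (int o = 0; o < 25; ++o) {
      const R_xlen_t off = (o % 5) + (R_xlen_t)(o / 5) * Hp;
      if (sw.nrow[o])
        dgemm_("N", "N", sw.nrow[o], (int)(tp - off), Cin, 1.0,
               sw.wk[o].data(), sw.nrow[o], xp.data() + off * Cin, Cin, 1.0,
               opad.data() + sw.row0[o], Wc);
    }
    // pool branch: 3x3 stride-1 max over the pad-1 ring of each tile
    for (int s = 0; s < nb; ++s)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const R_xlen_t pcol = (R_xlen_t)s * H * W + (R_xlen_t)j * H + i;
          double *pd = ptile.data() + pcol * Cin;
          const R_xlen_t base =
            (R_xlen_t)s * tileP + (R_xlen_t)(j + 1) * Hp + (i + 1);
          int *bp = best.begin() + ((R_xlen_t)(n0 + s) * H * W +
                                    (R_xlen_t)j * H + i) * Cin;
          const double *c0 = xp.data() + base * Cin;
          for (int ci = 0; ci < Cin; ++ci) { pd[ci] = c0[ci]; bp[ci] = 1; }
          int idx = 1;
          for (int b = 0; b < 3; ++b)
            for (int a = 0; a < 3; ++a) {
              if (a == 0 && b == 0) continue;
              ++idx;
              const double *s2 =
                xp.data() + (base + a + (R_xlen_t)b * Hp) * Cin;
              for (int ci = 0; ci < Cin; ++ci)
                if (s2[ci] > pd[ci]) { pd[ci] = s2[ci]; bp[ci] = idx; }
            }
        }
    if (w4)
      dgemm_("N", "N", w4, H * W * nb, Cin, 1.0, pw.data(), w4,
             ptile.data(), Cin, 0.0, ptmp.data(), w4);
    // assemble output columns
    for (int s = 0; s < nb; ++s) {
      double *yd = y.begin() + (R_xlen_t)(n0 + s) * H * W * Wtot;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const R_xlen_t vcol = (R_xlen_t)j * H + i;
          const double *oc =
            opad.data() + ((R_xlen_t)s * tileP + (R_xlen_t)j * Hp + i) * Wc;
          double *yc = yd + vcol * Wtot;
          for (int r = 0; r < Wc; ++r) yc[r] = oc[r] + bias[r];
          const double *pt =
            ptmp.data() + ((R_xlen_t)s * H * W + vcol) * w4;
          for (int r = 0; r < w4; ++r) yc[Wc + r] = pt[r] + bias[Wc + r];
        }
    }
  }
  return R_NilValue;
}

// [[Rcpp::export(name = ".cpp_eff_bwd")]]
List cpp_eff_bwd(NumericMatrix x1, NumericMatrix x2, NumericMatrix dy,
                 IntegerMatrix best, int H, int W, int N, NumericVector W1,
                 NumericVector W3, NumericVector W5, NumericVector Wp,
                 IntegerVector widths, NumericMatrix dx1,
                 NumericMatrix dx2) {
  const int C1 = x1.nrow(), C2 = x2.nrow();
  const int Cin = C1 + C2;
  const int w1 = widths[0], w2 = widths[1], w3 = widths[2], w4 = widths[3];
  const int Wtot = w1 + w2 + w3 + w4, Wc = w1 + w2 + w3;
  const int Hp = H + 4, Wp_ = W + 4, tileP = Hp * Wp_;

  const bool use_expand = Cin >= 64;
  const auto groups = make_groups(w1, w2, w3, Hp);
  const int Rtot = w1 + 9 * w2 + 25 * w3;
  std::vector<double> wexp, dwexp;
  StackedW sw{w1, w2, w3, Cin};
  if (use_expand) {
    wexp = make_wexp(groups, Rtot, Cin, W1.begin(), W3.begin(), W5.begin());
    dwexp.assign((size_t)Rtot * Cin, 0.0);
  } else
    sw.build(W1.begin(), W3.begin(), W5.begin());
  std::vector<double> pw((size_t)w4 * Cin);
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < w4; ++co)
      pw[co + (size_t)w4 * ci] = Wp[co + (R_xlen_t)w4 * ci];

  // stacked per-offset weight-gradient accumulators (shift-GEMM path)
  std::vector<std::vector<double>> dwk(25);
  if (!use_expand)
    for (int o = 0; o < 25; ++o)
      dwk[o].assign((size_t)sw.nrow[o] * Cin, 0.0);
  std::vector<double> dpw((size_t)w4 * Cin, 0.0);
  NumericVector db(Wtot);

  std::vector<double> xp((size_t)Cin * tileP * NB);
  std::vector<double> dypad((size_t)Wc * tileP * NB);
  std::vector<double> dxp((size_t)Cin * tileP * NB);
  std::vector<double> D(use_expand ? (size_t)Rtot * tileP * NB : 0);
  std::vector<double> ptile((size_t)Cin * H * W * NB);
  std::vector<double> dy4((size_t)w4 * H * W * NB);
  std::vector<double> dP((size_t)Cin * H * W * NB);

  for (int n0 = 0; n0 < N; n0 += NB) {
    const int nb = std::min(NB, N - n0);
    const R_xlen_t tp = (R_xlen_t)tileP * nb;
    build_tile(xp, x1.begin(), C1, C2 ? x2.begin() : nullptr, C2, H, W, n0,
               nb);
    std::fill(dypad.begin(), dypad.begin() + (size_t)Wc * tp, 0.0);
    std::fill(dxp.begin(), dxp.begin() + (size_t)Cin * tp, 0.0);
    for (int s = 0; s < nb; ++s) {
      const double *dyn = dy.begin() + (R_xlen_t)(n0 + s) * H * W * Wtot;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const R_xlen_t vcol = (R_xlen_t)j * H + i;
          const double *dc = dyn + vcol * Wtot;
          double *dpad = dypad.data() +
            ((R_xlen_t)s * tileP + (R_xlen_t)j * Hp + i) * Wc;
          for (int r = 0; r < Wc; ++r) { dpad[r] = dc[r]; db[r] += dc[r]; }
          double *d4 = dy4.data() + ((R_xlen_t)s * H * W + vcol) * w4;
          for (int r = 0; r < w4; ++r) {
            d4[r] = dc[Wc + r];
            db[Wc + r] += dc[Wc + r];
          }
        }
    }
    if (use_expand) {
      // scatter dy into the expanded row layout, then one GEMM per role
      std::fill(D.begin(), D.begin() + (size_t)Rtot * tp, 0.0);
      for (const auto &g : groups) {
        const R_xlen_t nc = tp - g.off;
        for (R_xlen_t c = 0; c < nc; ++c) {
          const double *src = dypad.data() + c * Wc + g.outRow;
          double *dst = D.data() + (c + g.off) * Rtot + g.eRow;
          for (int r = 0; r < g.w; ++r) dst[r] = src[r];
        }
      }
      dgemm_("N", "T", Rtot, Cin, (int)tp, 1.0, D.data(), Rtot, xp.data(),
             Cin, 1.0, dwexp.data(), Rtot);
      dgemm_("T", "N", Cin, (int)tp, Rtot, 1.0, wexp.data(), Rtot, D.data(),
             Rtot, 1.0, dxp.data(), Cin);
    } else
    for (int o = 0; o < 25; ++o) {
      if (!sw.nrow[o]) continue;
      const R_xlen_t off = (o % 5) + (R_xlen_t)(o / 5) * Hp;
      const int Mv = (int)(tp - off);
      dgemm_("N", "T", sw.nrow[o], Cin, Mv, 1.0,
             dypad.data() + sw.row0[o], Wc, xp.data() + off * Cin, Cin, 1.0,
             dwk[o].data(), sw.nrow[o]);
      dgemm_("T", "N", Cin, Mv, sw.nrow[o], 1.0, sw.wk[o].data(),
             sw.nrow[o], dypad.data() + sw.row0[o], Wc, 1.0,
             dxp.data() + off * Cin, Cin);
    }
    if (w4) {
      // rebuild the pooled tile from the argmax record, then dW and dP
      for (int s = 0; s < nb; ++s)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const R_xlen_t vcol = (R_xlen_t)s * H * W + (R_xlen_t)j * H + i;
            const R_xlen_t base =
              (R_xlen_t)s * tileP + (R_xlen_t)(j + 1) * Hp + (i + 1);
            const int *bp = best.begin() + ((R_xlen_t)(n0 + s) * H * W +
                                            (R_xlen_t)j * H + i) * Cin;
            double *pd = ptile.data() + vcol * Cin;
            for (int ci = 0; ci < Cin; ++ci) {
              const int k = bp[ci] - 1;
              pd[ci] =
                xp[(base + (k % 3) + (R_xlen_t)(k / 3) * Hp) * Cin + ci];
            }
          }
      dgemm_("N", "T", w4, Cin, H * W * nb, 1.0, dy4.data(), w4,
             ptile.data(), Cin, 1.0, dpw.data(), w4);
      dgemm_("T", "N", Cin, H * W * nb, w4, 1.0, pw.data(), w4, dy4.data(),
             w4, 0.0, dP.data(), Cin);
      for (int s = 0; s < nb; ++s)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const R_xlen_t vcol = (R_xlen_t)s * H * W + (R_xlen_t)j * H + i;
            const R_xlen_t base =
              (R_xlen_t)s * tileP + (R_xlen_t)(j + 1) * Hp + (i + 1);
            const int *bp = best.begin() + ((R_xlen_t)(n0 + s) * H * W +
                                            (R_xlen_t)j * H + i) * Cin;
            const double *dPc = dP.data() + vcol * Cin;
            for (int ci = 0; ci < Cin; ++ci) {
              const int k = bp[ci] - 1;
              dxp[(base + (k % 3) + (R_xlen_t)(k / 3) * Hp) * Cin + ci] +=
                dPc[ci];
            }
          }
    }
    // unpad and split into the two input blocks
    for (int s = 0; s < nb; ++s)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const R_xlen_t vcol =
            (R_xlen_t)(n0 + s) * H * W + (R_xlen_t)j * H + i;
          const double *sp = dxp.data() +
            ((R_xlen_t)s * tileP + (R_xlen_t)(j + 2) * Hp + i + 2) * Cin;
          std::memcpy(dx1.begin() + vcol * C1, sp, sizeof(double) * C1);
          if (C2)
            std::memcpy(dx2.begin() + vcol * C2, sp + C1,
                        sizeof(double) * C2);
        }
  }

  // unstack the weight gradients back into branch layout
  NumericVector dW1((R_xlen_t)w1 * Cin), dW3((R_xlen_t)w2 * Cin * 9),
    dW5((R_xlen_t)w3 * Cin * 25), dWp((R_xlen_t)w4 * Cin);
  if (use_expand) {
    for (const auto &g : groups) {
      double *dst = g.branch == 0 ? dW1.begin()
                    : (g.branch == 1 ? dW3.begin() : dW5.begin());
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < g.w; ++co)
          dst[co + (R_xlen_t)g.w * ci + (R_xlen_t)g.w * Cin * g.kidx] =
            dwexp[g.eRow + co + (size_t)Rtot * ci];
    }
    for (R_xlen_t t = 0; t < (R_xlen_t)w4 * Cin; ++t) dWp[t] = dpw[t];
    return List::create(_["dW1"] = dW1, _["dW3"] = dW3, _["dW5"] = dW5,
                        _["dWp"] = dWp, _["db"] = db);
  }
  for (int o = 0; o < 25; ++o) {
    const int di = o % 5, dj = o / 5;
    const bool mid = di >= 1 && di <= 3 && dj >= 1 && dj <= 3;
    const bool ctr = di == 2 && dj == 2;
    const double *src = dwk[o].data();
    int at = 0;
    if (ctr) {
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < w1; ++co)
          dW1[co + (R_xlen_t)w1 * ci] = src[co + (size_t)sw.nrow[o] * ci];
      at += w1;
    }
    if (mid) {
      const int k3 = (di - 1) + 3 * (dj - 1);
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < w2; ++co)
          dW3[co + (R_xlen_t)w2 * ci + (R_xlen_t)w2 * Cin * k3] =
            src[at + co + (size_t)sw.nrow[o] * ci];
      at += w2;
    }
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < w3; ++co)
        dW5[co + (R_xlen_t)w3 * ci + (R_xlen_t)w3 * Cin * o] =
          src[at + co + (size_t)sw.nrow[o] * ci];
  }
  for (R_xlen_t t = 0; t < (R_xlen_t)w4 * Cin; ++t) dWp[t] = dpw[t];
  return List::create(_["dW1"] = dW1, _["dW3"] = dW3, _["dW5"] = dW5,
                      _["dWp"] = dWp, _["db"] = db);
}

// Fused batch-norm + ReLU forward, writing into the caller's buffer y.
// Returns the per-channel statistics used (mean and 1/sd): the backward
// pass recomputes normalized values on the fly instead of caching them.
// [[Rcpp::export(name = ".cpp_bnrelu_fwd")]]
List cpp_bnrelu_fwd(NumericMatrix x, NumericVector gamma, NumericVector beta,
                    NumericVector run_mean, NumericVector run_var,
                    bool training, double momentum, double eps,
                    NumericMatrix y) {
  const int C = x.nrow();
  const R_xlen_t M = x.ncol();
  NumericVector mu(C), var_(C);
  const double *xd = x.begin();
  if (training) {
    std::vector<double> s(C, 0.0), ss(C, 0.0);
    for (R_xlen_t c = 0; c < M; ++c) {
      const double *col = xd + c * C;
      for (int i = 0; i < C; ++i) {
        s[i] += col[i];
        ss[i] += col[i] * col[i];
      }
    }
    for (int i = 0; i < C; ++i) {
      mu[i] = s[i] / M;
      var_[i] = std::max(ss[i] / M - mu[i] * mu[i], 0.0);
    }
  } else {
    for (int i = 0; i < C; ++i) { mu[i] = run_mean[i]; var_[i] = run_var[i]; }
  }
  NumericVector inv_sd(C), new_mean(C), new_var(C);
  std::vector<double> a(C), b2(C);
  for (int i = 0; i < C; ++i) {
    inv_sd[i] = 1.0 / std::sqrt(var_[i] + eps);
    a[i] = gamma[i] * inv_sd[i];
    b2[i] = beta[i] - mu[i] * a[i];
    new_mean[i] = training ? (1 - momentum) * run_mean[i] + momentum * mu[i]
                           : run_mean[i];
    new_var[i] = training ? (1 - momentum) * run_var[i] + momentum * var_[i]
                          : run_var[i];
  }
  double *yd = y.begin();
  for (R_xlen_t c = 0; c < M; ++c) {
    const double *col = xd + c * C;
    double *yc = yd + c * C;
    for (int i = 0; i < C; ++i) {
      const double v = a[i] * col[i] + b2[i];
      yc[i] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["mu"] = mu, _["inv_sd"] = inv_sd,
                      _["run_mean"] = new_mean, _["run_var"] = new_var);
}

// Fused backward, writing into the caller's buffer dx. Recomputes the
// normalized values and the ReLU mask from x.
// [[Rcpp::export(name = ".cpp_bnrelu_bwd")]]
List cpp_bnrelu_bwd(NumericMatrix x, NumericMatrix dy, NumericVector gamma,
                    NumericVector beta, NumericVector mu,
                    NumericVector inv_sd, bool batch_stats,
                    NumericMatrix dx) {
  const int C = x.nrow();
  const R_xlen_t M = x.ncol();
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> a(C), b2(C), sgy(C, 0.0), sg(C, 0.0);
  for (int i = 0; i < C; ++i) {
    a[i] = gamma[i] * inv_sd[i];
    b2[i] = beta[i] - mu[i] * a[i];
  }
  const double *xd = x.begin(), *dyd = dy.begin();
  for (R_xlen_t c = 0; c < M; ++c) {
    const double *col = xd + c * C, *dc = dyd + c * C;
    for (int i = 0; i < C; ++i) {
      const double m = (a[i] * col[i] + b2[i] > 0) ? 1.0 : 0.0;
      sgy[i] += m * dc[i] * (col[i] - mu[i]);
      sg[i] += m * dc[i];
    }
  }
  for (int i = 0; i < C; ++i) {
    dgamma[i] = sgy[i] * inv_sd[i];
    dbeta[i] = sg[i];
  }
  // dx = a * (t - mean(t) - xhat * mean(t * xhat)) under batch statistics,
  // where t is the ReLU-masked upstream gradient
  const double invM = batch_stats ? 1.0 / M : 0.0;
  double *dxd = dx.begin();
  for (R_xlen_t c = 0; c < M; ++c) {
    const double *col = xd + c * C, *dc = dyd + c * C;
    double *dxc = dxd + c * C;
    for (int i = 0; i < C; ++i) {
      const double m = (a[i] * col[i] + b2[i] > 0) ? 1.0 : 0.0;
      const double xh = (col[i] - mu[i]) * inv_sd[i];
      dxc[i] = a[i] * (m * dc[i] - sg[i] * invM - xh * dgamma[i] * invM);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
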