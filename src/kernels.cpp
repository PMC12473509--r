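#include <RcppArmadillo.h>
#include <cstring>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout convention for image batches: numeric array (h, w, M, c), column-major,
// where M indexes frames (windows concatenated in window-major order).
// Convolutions are fixed 3x3; pad = 0 (valid) or 1 (same).
// Weight matrices: (9*cin) x cout with row index q = ki + 3*kj + 9*c.

// Fast double-precision exp: Cody-Waite range reduction + degree-11 Taylor,
// relative error < 1e-12 on [-700, 700]; branch-free core so the compiler can
// vectorize loops over it.
static inline double fast_exp(double x) {
  // branch-free clamps (max/min via fabs) keep the surrounding loops
  // vectorizable; arguments beyond +-700 would over/underflow anyway
  x = 0.5 * (x - 700.0 + __builtin_fabs(x + 700.0));
  x = 0.5 * (x + 700.0 - __builtin_fabs(x - 700.0));
  const double LOG2E = 1.4426950408889634074;
  const double C1 = 6.93147180369123816490e-01;
  const double C2 = 1.90821492927058770002e-10;
  const double shifter = 6755399441055744.0;      // 1.5 * 2^52
  double t0 = x * LOG2E + shifter;                // round-to-nearest in low bits
  double n = t0 - shifter;
  double r = x - n * C1 - n * C2;
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320 + r * (1.0 / 362880 + r * (1.0 / 3628800 +
             r * (1.0 / 39916800)))))))))));
  // scale by 2^n through integer exponent arithmetic; n is recovered from the
  // magic-number bits without a float->int conversion (SIMD-friendly)
  int64_t ni, bits;
  std::memcpy(&ni, &t0, 8);
  std::memcpy(&bits, &p, 8);
  bits += (ni - 4841369599423283200LL) << 52;     // bits(shifter) = 0x4338...
  double out;
  std::memcpy(&out, &bits, 8);
  return out;
}

// [[Rcpp::export]]
NumericVector fast_exp_vec(NumericVector x) {
  NumericVector y(x.size());
  const double* __restrict xp = x.begin();
  double* __restrict yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = fast_exp(xp[i]);
  return y;
}

static inline double sigmoid_d(double x) {
  const double t = 1.0 / (1.0 + fast_exp(-__builtin_fabs(x)));
  const double sgn = __builtin_copysign(1.0, x);
  return 0.5 * (1.0 - sgn) + sgn * t;        // t for x>=0, 1-t otherwise
}

// SiLU x * sigmoid(x), elementwise, shape-preserving
// [[Rcpp::export]]
NumericVector silu_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* __restrict xp = x.begin();
  double* __restrict yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] * sigmoid_d(xp[i]);
  y.attr("dim") = x.attr("dim");
  return y;
}

// d/dx [x*sigmoid(x)] = s(1 + x(1-s))
// [[Rcpp::export]]
NumericVector silu_bw_cpp(NumericVector dout, NumericVector x) {
  NumericVector dx(x.size());
  const double* __restrict dp = dout.begin();
  const double* __restrict xp = x.begin();
  double* __restrict op = dx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double s = sigmoid_d(xp[i]);
    op[i] = dp[i] * (s * (1.0 + xp[i] * (1.0 - s)));
  }
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// im2col transposed layout: colT is (npix x 9cin), column q = ki + 3*kj + 9*c
// contiguous over output pixels (oi fastest), enabling memcpy row copies.
static void im2colT_chunk(const double* xp, int h, int w, int M, int cin,
                          int oh, int ow, int pad, int m0, int mc,
                          arma::mat& colT) {
  const size_t npix = (size_t)oh * ow * mc;
  for (int c = 0; c < cin; ++c) {
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int q = ki + 3 * kj + 9 * c;
        double* dst0 = colT.colptr(q);
        if (pad) std::memset(dst0, 0, npix * sizeof(double));
        const int oi0 = std::max(0, pad - ki);           // valid oi range
        const int oi1 = std::min(oh, h + pad - ki);      // exclusive
        if (oi1 <= oi0) continue;
        for (int ml = 0; ml < mc; ++ml) {
          const double* xim = xp + (size_t)h * w * ((size_t)(m0 + ml) + (size_t)M * c);
          for (int oj = 0; oj < ow; ++oj) {
            const int ij = oj + kj - pad;
            if (ij < 0 || ij >= w) continue;
            const double* src = xim + (size_t)h * ij + (oi0 + ki - pad);
            double* dst = dst0 + (size_t)oh * (oj + (size_t)ow * ml) + oi0;
            std::memcpy(dst, src, (size_t)(oi1 - oi0) * sizeof(double));
          }
        }
      }
    }
  }
}

static int chunk_size(int cin, int oh, int ow) {
  // keep the im2col buffer around the L2 cache size
  double per_img = 9.0 * cin * oh * ow * 8.0;
  return (int)std::max(1.0, 2e6 / per_img);
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, int h, int w, int M, int cin,
                        const arma::mat& W, const arma::vec& b, int pad) {
  const int oh = h + 2 * pad - 2, ow = w + 2 * pad - 2;
  const int cout = W.n_cols;
  NumericVector y((size_t)oh * ow * M * cout);
  const double* xp = x.begin();
  double* yp = y.begin();
  const int chunk = chunk_size(cin, oh, ow);
  arma::mat colT((size_t)oh * ow * chunk, 9 * cin);
  for (int m0 = 0; m0 < M; m0 += chunk) {
    const int mc = std::min(chunk, M - m0);
    const size_t npix = (size_t)oh * ow * mc;
    arma::mat colv(colT.memptr(), npix, 9 * cin, false, true);
    im2colT_chunk(xp, h, w, M, cin, oh, ow, pad, m0, mc, colv);
    arma::mat Yc = colv * W;  // npix x cout, plain dgemm
    for (int c2 = 0; c2 < cout; ++c2) {
      double* dst = yp + (size_t)oh * ow * ((size_t)m0 + (size_t)M * c2);
      const double* src = Yc.colptr(c2);
      const double bb = b(c2);
      for (size_t i = 0; i < npix; ++i) dst[i] = src[i] + bb;
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, M, cout);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, int h, int w, int M, int cin,
               const arma::mat& W, NumericVector dy, int pad, bool want_dx) {
  const int oh = h + 2 * pad - 2, ow = w + 2 * pad - 2;
  const int cout = W.n_cols;
  NumericVector dx(want_dx ? (size_t)h * w * M * cin : 0);
  arma::mat dW(9 * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const int chunk = chunk_size(cin, oh, ow);
  arma::mat colT((size_t)oh * ow * chunk, 9 * cin);
  for (int m0 = 0; m0 < M; m0 += chunk) {
    const int mc = std::min(chunk, M - m0);
    const size_t npix = (size_t)oh * ow * mc;
    arma::mat colv(colT.memptr(), npix, 9 * cin, false, true);
    im2colT_chunk(xp, h, w, M, cin, oh, ow, pad, m0, mc, colv);
    arma::mat dYc(npix, cout);
    for (int c2 = 0; c2 < cout; ++c2) {
      const double* src = dyp + (size_t)oh * ow * ((size_t)m0 + (size_t)M * c2);
      std::copy(src, src + npix, dYc.colptr(c2));
    }
    dW += colv.t() * dYc;        // dgemm TN, no explicit transpose copy
    db += arma::sum(dYc, 0).t();
    if (!want_dx) continue;
    arma::mat dcolT = dYc * W.t();  // npix x 9cin
    // col2im scatter-add, contiguous over oi
    for (int c = 0; c < cin; ++c) {
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          const int q = ki + 3 * kj + 9 * c;
          const double* src0 = dcolT.colptr(q);
          const int oi0 = std::max(0, pad - ki);
          const int oi1 = std::min(oh, h + pad - ki);
          if (oi1 <= oi0) continue;
          for (int ml = 0; ml < mc; ++ml) {
            double* xim = dxp + (size_t)h * w * ((size_t)(m0 + ml) + (size_t)M * c);
            for (int oj = 0; oj < ow; ++oj) {
              const int ij = oj + kj - pad;
              if (ij < 0 || ij >= w) continue;
              double* dst = xim + (size_t)h * ij + (oi0 + ki - pad);
              const double* src = src0 + (size_t)oh * (oj + (size_t)ow * ml) + oi0;
              for (int oi = 0; oi < oi1 - oi0; ++oi) dst[oi] += src[oi];
            }
          }
        }
      }
    }
  }
  if (want_dx) dx.attr("dim") = IntegerVector::create(h, w, M, cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 average pooling with stride 2 (floor; trailing row/col dropped)
// [[Rcpp::export]]
NumericVector avgpool2_fw(NumericVector x, int h, int w, int M, int c) {
  const int oh = h / 2, ow = w / 2;
  NumericVector y((size_t)oh * ow * M * c);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t nim = (size_t)M * c;
  for (size_t m = 0; m < nim; ++m) {
    const double* xi = xp + (size_t)h * w * m;
    double* yi = yp + (size_t)oh * ow * m;
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        const double* p = xi + 2 * oi + (size_t)h * (2 * oj);
        yi[oi + (size_t)oh * oj] = 0.25 * (p[0] + p[1] + p[h] + p[h + 1]);
      }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, M, c);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bw(NumericVector dy, int h, int w, int M, int c) {
  const int oh = h / 2, ow = w / 2;
  NumericVector dx((size_t)h * w * M * c);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t nim = (size_t)M * c;
  for (size_t m = 0; m < nim; ++m) {
    double* xi = dxp + (size_t)h * w * m;
    const double* yi = dyp + (size_t)oh * ow * m;
    for (int oj = 0; oj < ow; ++oj)
      for (int oi = 0; oi < oh; ++oi) {
        const double g = 0.25 * yi[oi + (size_t)oh * oj];
        double* p = xi + 2 * oi + (size_t)h * (2 * oj);
        p[0] += g; p[1] += g; p[h] += g; p[h + 1] += g;
      }
  }
  dx.attr("dim") = IntegerVector::create(h, w, M, c);
  return dx;
}

// Depthwise causal 1-D convolution over time within each window.
// x: E x M (M = nwin * L, window-major), wt: E x K, left zero padding.
// [[Rcpp::export]]
arma::mat dwconv_fw(const arma::mat& x, const arma::mat& wt, const arma::vec& b, int L) {
  const int E = x.n_rows, M = x.n_cols, K = wt.n_cols;
  const int nwin = M / L;
  arma::mat y(E, M);
  for (int wdx = 0; wdx < nwin; ++wdx) {
    const int off = wdx * L;
    for (int t = 0; t < L; ++t) {
      double* yc = y.colptr(off + t);
      std::memcpy(yc, b.memptr(), E * sizeof(double));
      for (int k = 0; k < K; ++k) {
        const int s = t - (K - 1) + k;
        if (s < 0) continue;
        const double* xc = x.colptr(off + s);
        const double* wc = wt.colptr(k);
        for (int e = 0; e < E; ++e) yc[e] += wc[e] * xc[e];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bw(const arma::mat& x, const arma::mat& wt, const arma::mat& dy, int L) {
  const int E = x.n_rows, M = x.n_cols, K = wt.n_cols;
  const int nwin = M / L;
  arma::mat dx(E, M, arma::fill::zeros);
  arma::mat dw(E, K, arma::fill::zeros);
  arma::vec db(E, arma::fill::zeros);
  for (int wdx = 0; wdx < nwin; ++wdx) {
    const int off = wdx * L;
    for (int t = 0; t < L; ++t) {
      const double* g = dy.colptr(off + t);
      double* dbp = db.memptr();
      for (int e = 0; e < E; ++e) dbp[e] += g[e];
      for (int k = 0; k < K; ++k) {
        const int s = t - (K - 1) + k;
        if (s < 0) continue;
        const double* xc = x.colptr(off + s);
        const double* wc = wt.colptr(k);
        double* dxc = dx.colptr(off + s);
        double* dwc = dw.colptr(k);
        for (int e = 0; e < E; ++e) {
          dwc[e] += g[e] * xc[e];
          dxc[e] += g[e] * wc[e];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Selective SSM scan (diagonal A, input-dependent delta/B/C shared over channels).
//   u, delta: E x M;  A: E x N (negative entries);  Bm, Cm: N x M;  Dskip: E
//   h_k = exp(A*delta_k) h_{k-1} + Bbar u_k,  y_k = C_k . h_k + Dskip u_k
//   Bbar exact ZOH: (exp(A d) - 1)/A * B;  euler: d * B.
// State resets to h0 = 0 at each window boundary (every L columns).
// [[Rcpp::export]]
arma::mat selective_scan_fw(const arma::mat& u, const arma::mat& delta, const arma::mat& A,
                            const arma::mat& Bm, const arma::mat& Cm, const arma::vec& Dskip,
                            int L, bool exact) {
  const int E = u.n_rows, M = u.n_cols, N = A.n_cols;
  const int nwin = M / L;
  arma::mat y(E, M);
  std::vector<double> hbuf((size_t)E * N);
  const double* Ap = A.memptr();
  const double* Dp = Dskip.memptr();
  for (int wdx = 0; wdx < nwin; ++wdx) {
    const int off = wdx * L;
    std::fill(hbuf.begin(), hbuf.end(), 0.0);
    for (int t = 0; t < L; ++t) {
      const int m = off + t;
      const double* dlt = delta.colptr(m);
      const double* uc = u.colptr(m);
      const double* Bc = Bm.colptr(m);
      const double* Cc = Cm.colptr(m);
      double* hp = hbuf.data();
      double* yc = y.colptr(m);
      for (int e = 0; e < E; ++e) yc[e] = Dp[e] * uc[e];
      for (int n = 0; n < N; ++n) {
        const double* Acol = Ap + (size_t)E * n;
        double* hcol = hp + (size_t)E * n;
        const double Bn = Bc[n];
        const double Cn = Cc[n];
        for (int e = 0; e < E; ++e) {
          const double ab = fast_exp(Acol[e] * dlt[e]);
          const double bb = exact ? (ab - 1.0) / Acol[e] * Bn : dlt[e] * Bn;
          const double hv = ab * hcol[e] + bb * uc[e];
          hcol[e] = hv;
          yc[e] += Cn * hv;
        }
      }
    }
  }
  return y;
}

// Fused backward: recomputes the forward hidden states window by window into
// scratch memory (cheap with the fast exp), then runs the adjoint recursion;
// nothing but the gradients crosses the R boundary.
// [[Rcpp::export]]
List selective_scan_bw(const arma::mat& u, const arma::mat& delta, const arma::mat& A,
                       const arma::mat& Bm, const arma::mat& Cm, const arma::vec& Dskip,
                       int L, bool exact, const arma::mat& dy) {
  const int E = u.n_rows, M = u.n_cols, N = A.n_cols;
  const int nwin = M / L;
  const size_t EN = (size_t)E * N;
  arma::cube hsave(E, N, L), absave(E, N, L);   // one window at a time
  arma::mat du(E, M, arma::fill::zeros), ddelta(E, M, arma::fill::zeros);
  arma::mat dA(E, N, arma::fill::zeros), dBm(N, M, arma::fill::zeros),
    dCm(N, M, arma::fill::zeros);
  arma::vec dD(E, arma::fill::zeros);
  std::vector<double> carry((size_t)E * N);
  const double* Ap = A.memptr();
  for (int wdx = 0; wdx < nwin; ++wdx) {
    const int off = wdx * L;
    // forward recomputation for this window
    for (int t = 0; t < L; ++t) {
      const int m = off + t;
      const double* dlt = delta.colptr(m);
      const double* uc = u.colptr(m);
      const double* Bc = Bm.colptr(m);
      double* hp = hsave.slice_memptr(t);
      double* abp = absave.slice_memptr(t);
      const double* hprev = (t == 0) ? nullptr : hsave.slice_memptr(t - 1);
      for (int n = 0; n < N; ++n) {
        const double* Acol = Ap + (size_t)E * n;
        double* hcol = hp + (size_t)E * n;
        const double* hprevcol = hprev ? hprev + (size_t)E * n : nullptr;
        double* abcol = abp + (size_t)E * n;
        const double Bn = Bc[n];
        for (int e = 0; e < E; ++e) {
          const double ab = fast_exp(Acol[e] * dlt[e]);
          abcol[e] = ab;
          const double bb = exact ? (ab - 1.0) / Acol[e] * Bn : dlt[e] * Bn;
          hcol[e] = ab * (hprevcol ? hprevcol[e] : 0.0) + bb * uc[e];
        }
      }
    }
    std::fill(carry.begin(), carry.end(), 0.0);
    for (int t = L - 1; t >= 0; --t) {
      const int m = off + t;
      const double* dlt = delta.colptr(m);
      const double* uc = u.colptr(m);
      const double* Bc = Bm.colptr(m);
      const double* Cc = Cm.colptr(m);
      const double* dyc = dy.colptr(m);
      const double* hp = hsave.slice_memptr(t);
      const double* abp = absave.slice_memptr(t);
      const double* hprev = (t == 0) ? nullptr : hsave.slice_memptr(t - 1);
      double* duc = du.colptr(m);
      double* ddl = ddelta.colptr(m);
      double* dBc = dBm.colptr(m);
      double* dCc = dCm.colptr(m);
      for (int e = 0; e < E; ++e) {
        dD(e) += dyc[e] * uc[e];
        duc[e] += Dskip(e) * dyc[e];
      }
      for (int n = 0; n < N; ++n) {
        const double* Acol = Ap + (size_t)E * n;
        const double* hcol = hp + (size_t)E * n;
        const double* abcol = abp + (size_t)E * n;
        const double* hpcol = hprev ? hprev + (size_t)E * n : nullptr;
        double* ccol = carry.data() + (size_t)E * n;
        const double Bn = Bc[n], Cn = Cc[n];
        double dCn = 0.0, dBn = 0.0, *dAcol = dA.colptr(n);
        for (int e = 0; e < E; ++e) {
          const double ab = abcol[e];
          const double adj = dyc[e] * Cn + ccol[e];     // adjoint of h_t[e,n]
          dCn += dyc[e] * hcol[e];
          const double hprev_e = hpcol ? hpcol[e] : 0.0;
          const double dab_state = adj * hprev_e;
          const double bbcoef = exact ? (ab - 1.0) / Acol[e] : dlt[e];
          const double bb = bbcoef * Bn;
          const double dbb = adj * uc[e];
          duc[e] += adj * bb;
          dBn += dbb * bbcoef;
          double dab_tot = dab_state;
          if (exact) {
            dab_tot += dbb * Bn / Acol[e];
            dAcol[e] += -dbb * (ab - 1.0) / (Acol[e] * Acol[e]) * Bn;
          } else {
            ddl[e] += dbb * Bn;
          }
          const double w = dab_tot * ab;
          ddl[e] += w * Acol[e];
          dAcol[e] += w * dlt[e];
          ccol[e] = adj * ab;                            // carry to t-1
        }
        dCc[n] = dCn;
        dBc[n] = dBn;
      }
    }
  }
  return List::create(_["du"] = du, _["ddelta"] = ddelta, _["dA"] = dA,
                      _["dB"] = dBm, _["dC"] = dCm, _["dD"] = dD);
}

// Fused training-time augmentation of one subregion clip: temporal linear
// resampling at speed r (reflected at the ends), per-channel affine jitter,
// clamp to [0,1].  x: (h, w, L, 3) numeric; returns same shape.
// [[Rcpp::export]]
NumericVector augment_clip_cpp(NumericVector x, int h, int w, int L, double r,
                               NumericVector scale, NumericVector offset) {
  NumericVector y((size_t)h * w * L * 3);
  const double* __restrict xp = x.begin();
  double* __restrict yp = y.begin();
  const size_t hw = (size_t)h * w;
  for (int c = 0; c < 3; ++c) {
    const double sc = scale[c], off = offset[c];
    for (int t = 0; t < L; ++t) {
      double u = (double)t * r;                 // 0-based position
      const double period = 2.0 * (L - 1);
      while (u >= period) u -= period;          // r < 2 keeps this cheap
      if (u > L - 1) u = period - u;
      int lo = (int)u; if (lo > L - 2) lo = L - 2;
      const double fr = u - lo;
      const double* __restrict a = xp + hw * ((size_t)lo + (size_t)L * c);
      const double* __restrict b = a + hw;
      double* __restrict o = yp + hw * ((size_t)t + (size_t)L * c);
      for (size_t i = 0; i < hw; ++i) {
        double v = (a[i] * (1.0 - fr) + b[i] * fr) * sc + off;
        v = 0.5 * (v + __builtin_fabs(v));            // max(v, 0)
        v = 0.5 * (v + 1.0 - __builtin_fabs(v - 1.0)); // min(v, 1)
        o[i] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(h, w, L, 3);
  return y;
}
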