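// 2-D convolution primitives for the generator/discriminator networks.
// Feature maps are R arrays [H, W, C, N] (column-major); weights [k, k, C, F].
// The patch matrix is stored transposed, (Ho*Wo) x (k*k*C), so that for a
// fixed kernel offset the inner loops write/read one contiguous column, and
// the forward product cols_t * W directly yields the [Ho, Wo, F] layout.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_t(const double* x, int H, int W, int C,
                     int k, int s, int p, int Ho, int Wo, arma::mat& cols_t) {
  const size_t npix = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* col = cols_t.colptr(kh + k * (kw + k * c));
        size_t q = 0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col[q++] = 0.0;
            continue;
          }
          const double* xw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + kh;
            col[q++] = (hi >= 0 && hi < H) ? xw[hi] : 0.0;
          }
        }
        (void)npix;
      }
    }
  }
}

static void col2im_t_acc(const arma::mat& cols_t, double* dx, int H, int W, int C,
                         int k, int s, int p, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* col = cols_t.colptr(kh + k * (kw + k * c));
        size_t q = 0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) { q += Ho; continue; }
          double* xw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho, ++q) {
            const int hi = ho * s - p + kh;
            if (hi >= 0 && hi < H) xw[hi] += col[q];
          }
        }
      }
    }
  }
}

static inline int out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

// ---- fast path for 3x3 / stride 1 / pad 1 ---------------------------------
// One full-matrix gemm per kernel offset on the (H*W) x C view of the input,
// followed by a boundary-aware shifted add. Same FLOPs as im2col but without
// materializing the patch matrix.

static inline int w_row3(int dh, int dw, int c) {
  return (dh + 1) + 3 * ((dw + 1) + 3 * c);
}

static void conv3_fw_sample(const double* x, double* y, const arma::mat& Wm,
                            const double* b, int H, int W, int C, int F,
                            arma::mat& Wo, arma::mat& Z) {
  const size_t HW = (size_t)H * W;
  arma::mat Xm(const_cast<double*>(x), HW, C, false, true);
  arma::mat Ym(y, HW, F, false, true);
  for (int f = 0; f < F; ++f) Ym.col(f).fill(b[f]);
  for (int dw = -1; dw <= 1; ++dw) {
    for (int dh = -1; dh <= 1; ++dh) {
      for (int c = 0; c < C; ++c) Wo.row(c) = Wm.row(w_row3(dh, dw, c));
      Z = Xm * Wo;  // (H*W) x F
      const int wo0 = dw < 0 ? -dw : 0, wo1 = W - 1 - (dw > 0 ? dw : 0);
      const int ho0 = dh < 0 ? -dh : 0, len = H - (dh < 0 ? -dh : dh);
      for (int f = 0; f < F; ++f) {
        for (int wo = wo0; wo <= wo1; ++wo) {
          double* dst = Ym.colptr(f) + (size_t)H * wo + ho0;
          const double* src = Z.colptr(f) + (size_t)H * (wo + dw) + ho0 + dh;
          for (int i = 0; i < len; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static void conv3_bw_sample(const double* x, const double* dy,
                            const arma::mat& Wm, double* dx, double* dwacc,
                            double* dbacc, int H, int W, int C, int F,
                            bool need_dx, bool need_dw,
                            arma::mat& Wo, arma::mat& Z) {
  const size_t HW = (size_t)H * W;
  arma::mat Xm(const_cast<double*>(x), HW, C, false, true);
  arma::mat dYm(const_cast<double*>(dy), HW, F, false, true);
  if (need_dw) {
    arma::vec dbv(dbacc, F, false, true);
    dbv += arma::sum(dYm, 0).t();
  }
  for (int dw = -1; dw <= 1; ++dw) {
    for (int dh = -1; dh <= 1; ++dh) {
      const int wo0 = dw < 0 ? -dw : 0, wo1 = W - 1 - (dw > 0 ? dw : 0);
      const int ho0 = dh < 0 ? -dh : 0, len = H - (dh < 0 ? -dh : dh);
      if (need_dx) {
        for (int c = 0; c < C; ++c) Wo.row(c) = Wm.row(w_row3(dh, dw, c));
        Z = dYm * Wo.t();  // (H*W) x C
        for (int c = 0; c < C; ++c) {
          double* dst = dx + HW * c;
          const double* src = Z.colptr(c);
          for (int wo = wo0; wo <= wo1; ++wo) {
            double* d2 = dst + (size_t)H * (wo + dw) + ho0 + dh;
            const double* s2 = src + (size_t)H * wo + ho0;
            for (int i = 0; i < len; ++i) d2[i] += s2[i];
          }
        }
      }
      if (need_dw) {
        // One gemm over the contiguous hull of the valid region, then
        // subtract the few rows that wrap across column boundaries.
        const int s_off = dh + H * dw;
        const size_t qa = (size_t)H * wo0 + ho0;
        const size_t qb = (size_t)H * wo1 + ho0 + len - 1;
        arma::mat dWo = Xm.rows(qa + s_off, qb + s_off).t() * dYm.rows(qa, qb);
        if (dh == 1) {
          for (int wo = wo0; wo < wo1; ++wo) {
            const size_t q = (size_t)H * wo + H - 1;
            for (int c = 0; c < C; ++c)
              for (int f = 0; f < F; ++f)
                dWo(c, f) -= Xm(q + s_off, c) * dYm(q, f);
          }
        } else if (dh == -1) {
          for (int wo = wo0 + 1; wo <= wo1; ++wo) {
            const size_t q = (size_t)H * wo;
            for (int c = 0; c < C; ++c)
              for (int f = 0; f < F; ++f)
                dWo(c, f) -= Xm(q + s_off, c) * dYm(q, f);
          }
        }
        arma::mat dWm(dwacc, (size_t)9 * C, F, false, true);
        for (int c = 0; c < C; ++c) dWm.row(w_row3(dh, dw, c)) += dWo.row(c);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], F = wdim[3];
  if (wdim[1] != k || wdim[2] != C) stop("weight dims inconsistent with input");
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  NumericVector out((size_t)Ho * Wo * F * N);

  if (k == 3 && stride == 1 && pad == 1) {  // Ho == H, Wo == W
    arma::mat Wof(C, F), Zbuf;
    for (int n = 0; n < N; ++n)
      conv3_fw_sample(x.begin() + (size_t)H * W * C * n,
                      out.begin() + (size_t)H * W * F * n,
                      Wm, b.begin(), H, W, C, F, Wof, Zbuf);
    out.attr("dim") = IntegerVector::create(H, W, F, N);
    return out;
  }

  arma::mat cols_t((size_t)Ho * Wo, (size_t)k * k * C);
  arma::rowvec bv(const_cast<double*>(b.begin()), F, false, true);

  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, cols_t);
    arma::mat y(out.begin() + (size_t)Ho * Wo * F * n, (size_t)Ho * Wo, F, false, true);
    y = cols_t * Wm;                    // (Ho*Wo) x F == [Ho, Wo, F] layout
    y.each_row() += bv;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return out;
}

// Computes only the requested gradients: dx (input), dw/db (parameters).
// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy, int stride, int pad,
                bool need_dx = true, bool need_dw = true) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], F = wdim[3];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  NumericVector dw(need_dw ? (size_t)k * k * C * F : 0);
  NumericVector db(need_dw ? F : 0);

  if (k == 3 && stride == 1 && pad == 1) {
    arma::mat Wof(C, F), Zbuf;
    for (int n = 0; n < N; ++n)
      conv3_bw_sample(x.begin() + (size_t)H * W * C * n,
                      dy.begin() + (size_t)H * W * F * n,
                      Wm,
                      need_dx ? dx.begin() + (size_t)H * W * C * n : nullptr,
                      need_dw ? dw.begin() : nullptr,
                      need_dw ? db.begin() : nullptr,
                      H, W, C, F, need_dx, need_dw, Wof, Zbuf);
    if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
    if (need_dw) dw.attr("dim") = IntegerVector::create(k, k, C, F);
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  arma::mat cols_t;
  if (need_dw) cols_t.set_size((size_t)Ho * Wo, (size_t)k * k * C);

  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * F * n,
                 (size_t)Ho * Wo, F, false, true);
    if (need_dw) {
      im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, cols_t);
      arma::mat dWm(dw.begin(), (size_t)k * k * C, F, false, true);
      arma::vec dbv(db.begin(), F, false, true);
      dWm += cols_t.t() * dY;
      dbv += arma::sum(dY, 0).t();
    }
    if (need_dx) {
      arma::mat dcols_t = dY * Wm.t();  // (Ho*Wo) x (k*k*C)
      col2im_t_acc(dcols_t, dx.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo);
    }
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  if (need_dw) dw.attr("dim") = IntegerVector::create(k, k, C, F);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector nn_lrelu_fw(NumericVector x, double alpha) {
  NumericVector y(x.size());
  const double* xi = x.begin();
  double* yi = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yi[i] = xi[i] > 0 ? xi[i] : alpha * xi[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector nn_lrelu_bw(NumericVector x, NumericVector dy, double alpha) {
  NumericVector g(x.size());
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* gi = g.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) gi[i] = xi[i] > 0 ? di[i] : alpha * di[i];
  g.attr("dim") = x.attr("dim");
  return g;
}

// Per-channel gating and nearest-neighbour 2x upsampling kernels: single-pass
// loops that avoid materializing broadcast multiplier arrays in R.

// [[Rcpp::export]]
NumericVector nn_gate_fw(NumericVector x, IntegerVector xdim, NumericVector g) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  const double* xi = x.begin();
  double* yi = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double gc = g[c];
      const size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yi[off + i] = xi[off + i] * gc;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// returns list(dx, dg_raw) with dg_raw[c] = sum over H,W,N of dy * x
// [[Rcpp::export]]
List nn_gate_bw(NumericVector x, IntegerVector xdim, NumericVector g,
                NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx(x.size());
  NumericVector dg(C);
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* dxi = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double gc = g[c];
      const size_t off = HW * (c + (size_t)C * n);
      double acc = 0.0;
      for (size_t i = 0; i < HW; ++i) {
        dxi[off + i] = di[off + i] * gc;
        acc += di[off + i] * xi[off + i];
      }
      dg[c] += acc;
    }
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dg_raw"] = dg);
}

// [[Rcpp::export]]
NumericVector nn_up2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)4 * H * W * C * N);
  const double* xi = x.begin();
  double* yi = y.begin();
  const int H2 = 2 * H;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xi + (size_t)H * W * cn;
    double* yc = yi + (size_t)H2 * 2 * W * cn;
    for (int w = 0; w < W; ++w) {
      const double* col = xc + (size_t)H * w;
      double* c0 = yc + (size_t)H2 * (2 * w);
      double* c1 = yc + (size_t)H2 * (2 * w + 1);
      for (int h = 0; h < H; ++h) {
        const double v = col[h];
        c0[2 * h] = v; c0[2 * h + 1] = v;
        c1[2 * h] = v; c1[2 * h + 1] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H2, 2 * W, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector nn_up2_bw(NumericVector dy, IntegerVector ydim) {
  const int H2 = ydim[0], W2 = ydim[1], C = ydim[2], N = ydim[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  const double* di = dy.begin();
  double* dxi = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* yc = di + (size_t)H2 * W2 * cn;
    double* xc = dxi + (size_t)H * W * cn;
    for (int w = 0; w < W; ++w) {
      const double* c0 = yc + (size_t)H2 * (2 * w);
      const double* c1 = yc + (size_t)H2 * (2 * w + 1);
      double* col = xc + (size_t)H * w;
      for (int h = 0; h < H; ++h)
        col[h] = c0[2 * h] + c0[2 * h + 1] + c1[2 * h] + c1[2 * h + 1];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
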