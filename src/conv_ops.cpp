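// Convolution primitives for the autoencoder.
//
// Layout conventions (all column-major, matching R arrays):
//   feature maps  x : [H, W, C, N]
//   conv weights  w : [kh, kw, Cin, Cout]
//   depthwise     w : [kh, kw, C]
// Convolution here is cross-correlation (no kernel flip), the deep-learning
// convention. im2col row ordering is (ki, kj, ci) fastest-first so that a
// weight array [kh, kw, Cin, Cout] can be viewed directly as a
// (kh*kw*Cin) x Cout matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array [H, W, C, N]");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather input patches into col (K x P), K = kh*kw*C, P = Ho*Wo.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::mat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      double* cp = col.colptr(oi + (size_t)Ho * oj);
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = oj * stride + kj - pad;
          const bool jok = (jj >= 0 && jj < W);
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = oi * stride + ki - pad;
            cp[ki + kh * (kj + (size_t)kw * ci)] =
              (jok && ii >= 0 && ii < H) ? xc[ii + (size_t)H * jj] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add col (K x P) back onto an input-shaped accumulator.
static void col2im(const arma::mat& col, double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const double* cp = col.colptr(oi + (size_t)Ho * oj);
      for (int ci = 0; ci < C; ++ci) {
        double* xc = x + (size_t)H * W * ci;
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xc[ii + (size_t)H * jj] += cp[ki + kh * (kj + (size_t)kw * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int dx[4]; get_dims4(x, dx);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 4) stop("conv weight must be [kh, kw, Cin, Cout]");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output would be empty");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, col);
    arma::mat o(out.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    o = col.t() * wm;
    o.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  int dx[4]; get_dims4(x, dx);
  int dg[4]; get_dims4(gy, dg);
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) stop("conv2d_bw: gradient dims inconsistent");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dxv((R_xlen_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw;
  NumericVector dbv(Cout);

  arma::mat dwm(dwv.begin(), K, Cout, false, true);
  arma::rowvec dbm(dbv.begin(), Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat g(const_cast<double*>(gy.begin()) + (size_t)P * Cout * n,
                P, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, col);
    dwm += col * g;
    dbm += arma::sum(g, 0);
    arma::mat dcol = wm * g.t();               // K x P
    col2im(dcol, dxv.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed convolution (adjoint of cpp_conv2d). The weight is stored in
// conv layout [kh, kw, Cout_t, Cin_t], i.e. as the stride-`stride` conv that
// maps the *output* of this layer back to its input.
// [[Rcpp::export]]
NumericVector cpp_tconv2d(NumericVector u, NumericVector w, NumericVector b,
                          int stride, int pad) {
  int du[4]; get_dims4(u, du);
  IntegerVector dw = w.attr("dim");
  const int h = du[0], wd = du[1], Cin = du[2], N = du[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[2];
  if (dw[3] != Cin) stop("tconv2d: channel mismatch");
  const int Hout = (h - 1) * stride - 2 * pad + kh;
  const int Wout = (wd - 1) * stride - 2 * pad + kw;
  const int K = kh * kw * Cout, P = h * wd;

  arma::mat wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  NumericVector out((R_xlen_t)Hout * Wout * Cout * N);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);

  for (int n = 0; n < N; ++n) {
    arma::mat g(const_cast<double*>(u.begin()) + (size_t)P * Cin * n,
                P, Cin, false, true);
    arma::mat dcol = wm * g.t();               // K x P
    double* op = out.begin() + (size_t)Hout * Wout * Cout * n;
    col2im(dcol, op, Hout, Wout, Cout, kh, kw, stride, pad);
    for (int c = 0; c < Cout; ++c) {
      double* oc = op + (size_t)Hout * Wout * c;
      const double bc = b[c];
      for (size_t i = 0; i < (size_t)Hout * Wout; ++i) oc[i] += bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_tconv2d_bw(NumericVector u, NumericVector w, NumericVector gv,
                    int stride, int pad) {
  int du[4]; get_dims4(u, du);
  int dg[4]; get_dims4(gv, dg);
  IntegerVector dw = w.attr("dim");
  const int h = du[0], wd = du[1], Cin = du[2], N = du[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[2];
  const int Hout = dg[0], Wout = dg[1];
  const int K = kh * kw * Cout, P = h * wd;

  arma::mat wm(const_cast<double*>(w.begin()), K, Cin, false, true);
  NumericVector duv((R_xlen_t)h * wd * Cin * N);
  duv.attr("dim") = IntegerVector::create(h, wd, Cin, N);
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw;
  NumericVector dbv(Cout);
  arma::mat dwm(dwv.begin(), K, Cin, false, true);

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* gp = gv.begin() + (size_t)Hout * Wout * Cout * n;
    im2col(gp, Hout, Wout, Cout, kh, kw, stride, pad, col);
    // du = stride-conv of gv with w
    arma::mat o(duv.begin() + (size_t)P * Cin * n, P, Cin, false, true);
    o = col.t() * wm;
    // dw accumulates u (as the conv output grad) against gv patches
    arma::mat g(const_cast<double*>(u.begin()) + (size_t)P * Cin * n,
                P, Cin, false, true);
    dwm += col * g;
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gp + (size_t)Hout * Wout * c;
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Hout * Wout; ++i) s += gc[i];
      dbv[c] += s;
    }
  }
  return List::create(_["dx"] = duv, _["dw"] = dwv, _["db"] = dbv);
}

// Depthwise 3x3-style conv, stride 1, same padding. w: [kh, kw, C].
// [[Rcpp::export]]
NumericVector cpp_dwconv2d(NumericVector x, NumericVector w, int pad) {
  int dx[4]; get_dims4(x, dx);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 3) stop("depthwise weight must be [kh, kw, C]");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1];
  if (dw[2] != C) stop("depthwise: channel mismatch");
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* oc = out.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < W; ++oj) {
        for (int oi = 0; oi < H; ++oi) {
          double s = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int jj = oj + kj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int ii = oi + ki - pad;
              if (ii < 0 || ii >= H) continue;
              s += xc[ii + (size_t)H * jj] * wc[ki + kh * kj];
            }
          }
          oc[oi + (size_t)H * oj] = s;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  int dx[4]; get_dims4(x, dx);
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1];
  NumericVector dxv(x.size());
  dxv.attr("dim") = x.attr("dim");
  NumericVector dwv(w.size());
  dwv.attr("dim") = dw;

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = gy.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* dxc = dxv.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dwv.begin() + (size_t)kh * kw * c;
      for (int oj = 0; oj < W; ++oj) {
        for (int oi = 0; oi < H; ++oi) {
          const double g = gc[oi + (size_t)H * oj];
          if (g == 0.0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int jj = oj + kj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int ii = oi + ki - pad;
              if (ii < 0 || ii >= H) continue;
              dxc[ii + (size_t)H * jj] += g * wc[ki + kh * kj];
              dwc[ki + kh * kj] += g * xc[ii + (size_t)H * jj];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv);
}
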