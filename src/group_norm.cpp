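// Fused Group Normalization + optional ReLU, forward and backward.
// x: [H, W, C, N]; channels are split into `groups` contiguous groups and
// normalized over (H, W, channels-in-group) per sample; gamma/beta are
// per-channel affine terms.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gn_relu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                     int groups, double eps, bool relu) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int cg = C / groups;
  const size_t m = (size_t)H * W * cg;

  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = dm; xhat.attr("dim") = dm;
  NumericVector ivar(groups * N);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xp = x.begin() + m * (g + (size_t)groups * n);
      double s = 0.0, ss = 0.0;
      for (size_t i = 0; i < m; ++i) { s += xp[i]; ss += xp[i] * xp[i]; }
      const double mu = s / m;
      const double var = ss / m - mu * mu;
      const double iv = 1.0 / std::sqrt(var + eps);
      ivar[g + groups * n] = iv;
      double* xh = xhat.begin() + m * (g + (size_t)groups * n);
      double* op = out.begin() + m * (g + (size_t)groups * n);
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c], be = beta[g * cg + c];
        const size_t off = (size_t)H * W * c;
        for (size_t i = 0; i < (size_t)H * W; ++i) {
          const double xv = (xp[off + i] - mu) * iv;
          xh[off + i] = xv;
          double y = ga * xv + be;
          if (relu && y < 0) y = 0;
          op[off + i] = y;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["ivar"] = ivar);
}

// [[Rcpp::export]]
List cpp_gn_relu_bw(NumericVector gy, NumericVector xhat, NumericVector ivar,
                    NumericVector gamma, NumericVector beta,
                    int groups, bool relu) {
  IntegerVector dm = xhat.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int cg = C / groups;
  const size_t m = (size_t)H * W * cg;

  NumericVector dx(xhat.size());
  dx.attr("dim") = dm;
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> dxh(m);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* gp = gy.begin() + m * (g + (size_t)groups * n);
      const double* xh = xhat.begin() + m * (g + (size_t)groups * n);
      const double iv = ivar[g + groups * n];
      double s1 = 0.0, s2 = 0.0;
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c], be = beta[g * cg + c];
        const size_t off = (size_t)H * W * c;
        double dgc = 0.0, dbc = 0.0;
        for (size_t i = 0; i < (size_t)H * W; ++i) {
          double gv = gp[off + i];
          if (relu && (ga * xh[off + i] + be) <= 0) gv = 0.0;
          dgc += gv * xh[off + i];
          dbc += gv;
          const double dh = gv * ga;
          dxh[off + i] = dh;
          s1 += dh * xh[off + i];
          s2 += dh;
        }
        dgamma[g * cg + c] += dgc;
        dbeta[g * cg + c] += dbc;
      }
      double* dp = dx.begin() + m * (g + (size_t)groups * n);
      const double a = s1 / m, b = s2 / m;
      for (size_t i = 0; i < m; ++i) {
        dp[i] = iv * (dxh[i] - b - xh[i] * a);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Per-channel multiplicative gate: out = x * gate[c, n] (broadcast over H, W).
// [[Rcpp::export]]
NumericVector cpp_channel_scale(NumericVector x, NumericVector gate) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  NumericVector out(x.size());
  out.attr("dim") = dm;
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double gcn = gate[c + (size_t)C * n];
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      double* op = out.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) op[i] = xp[i] * gcn;
    }
  }
  return out;
}
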