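#include <Rcpp.h>
using namespace Rcpp;

// Dense 2-D convolution kernels used by the autodiff engine.
// Tensor layout is column-major (H, W, C, B); weights are (K, K, Cin, Cout).
// Zero padding, integer stride; "convolution" here is cross-correlation,
// the usual CNN convention.

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int pad, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = out_size(H, K, pad, stride), Wo = out_size(W, K, pad, stride);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int bb = 0; bb < B; ++bb) {
    for (int co = 0; co < Cout; ++co) {
      const double bias = pb[co];
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bias;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < Cin; ++ci) {
            const double *xp = px + (static_cast<R_xlen_t>(bb) * Cin + ci) * H * W;
            const double *wp = pw + (static_cast<R_xlen_t>(co) * Cin + ci) * K * K;
            for (int kw = 0; kw < K; ++kw) {
              const int wi = w0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int hi = h0 + kh;
                if (hi < 0 || hi >= H) continue;
                acc += xp[hi + static_cast<R_xlen_t>(wi) * H] * wp[kh + kw * K];
              }
            }
          }
          py[ho + static_cast<R_xlen_t>(wo) * Ho +
             (static_cast<R_xlen_t>(bb) * Cout + co) * Ho * Wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad, int stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int bb = 0; bb < B; ++bb) {
    for (int co = 0; co < Cout; ++co) {
      const double *gp = pg + (static_cast<R_xlen_t>(bb) * Cout + co) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gp[ho + static_cast<R_xlen_t>(wo) * Ho];
          if (g == 0.0) continue;
          pgb[co] += g;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int ci = 0; ci < Cin; ++ci) {
            const double *xp = px + (static_cast<R_xlen_t>(bb) * Cin + ci) * H * W;
            double *gxp = pgx + (static_cast<R_xlen_t>(bb) * Cin + ci) * H * W;
            const double *wp = pw + (static_cast<R_xlen_t>(co) * Cin + ci) * K * K;
            double *gwp = pgw + (static_cast<R_xlen_t>(co) * Cin + ci) * K * K;
            for (int kw = 0; kw < K; ++kw) {
              const int wi = w0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int hi = h0 + kh;
                if (hi < 0 || hi >= H) continue;
                const R_xlen_t xi = hi + static_cast<R_xlen_t>(wi) * H;
                gwp[kh + kw * K] += xp[xi] * g;
                gxp[xi] += wp[kh + kw * K] * g;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Separable same-size blur with a 1-D kernel applied along rows then columns,
// zero padding. Used for windowed SSIM statistics; self-adjoint for
// symmetric kernels.
// [[Rcpp::export(name = ".cpp_sepconv2d")]]
NumericVector cpp_sepconv2d(NumericVector x, NumericVector k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1];
  R_xlen_t nplane = 1;
  for (int i = 2; i < xd.size(); ++i) nplane *= xd[i];
  const int K = k.size(), hw = (K - 1) / 2;
  NumericVector tmp(x.size()), y(x.size());
  y.attr("dim") = xd;
  const double *pk = k.begin();
  for (R_xlen_t p = 0; p < nplane; ++p) {
    const double *xp = x.begin() + p * H * W;
    double *tp = tmp.begin() + p * H * W;
    double *yp = y.begin() + p * H * W;
    // along H
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        const int lo = std::max(0, hw - h), hi = std::min(K, H - h + hw);
        for (int t = lo; t < hi; ++t) acc += xp[h + t - hw + static_cast<R_xlen_t>(w) * H] * pk[t];
        tp[h + static_cast<R_xlen_t>(w) * H] = acc;
      }
    }
    // along W
    for (int w = 0; w < W; ++w) {
      const int lo = std::max(0, hw - w), hi = std::min(K, W - w + hw);
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int t = lo; t < hi; ++t) acc += tp[h + static_cast<R_xlen_t>(w + t - hw) * H] * pk[t];
        yp[h + static_cast<R_xlen_t>(w) * H] = acc;
      }
    }
  }
  return y;
}
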