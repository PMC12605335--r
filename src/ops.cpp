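// Compiled kernels for the autodiff engine.
//
// Feature maps are stored as dense arrays with dim (H, W, N, C), channel
// slowest, so that channel concatenation is contiguous and per-channel
// broadcasts are cheap on the R side.  Convolution weights are matrices of
// shape (kh*kw*Cin) x Cout with row index r = ky + kh*(kx + kw*c): ky
// fastest, then kx, then input channel.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericMatrix out(Ho * Wo * N, kh * kw * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        double* op = &out(0, col);
        for (int n = 0; n < N; ++n) {
          const double* xnc = xp + (size_t)H * W * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - pw + kx;
            const size_t row0 = (size_t)Ho * (wo + (size_t)Wo * n);
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - ph + ky;
              if (hi < 0 || hi >= H) continue;
              op[row0 + ho] = xnc[hi + (size_t)H * wi];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector gx((size_t)H * W * N * C);
  double* gp = gx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int col = ky + kh * (kx + kw * c);
        const double* cp = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          double* gnc = gp + (size_t)H * W * (n + (size_t)N * c);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - pw + kx;
            if (wi < 0 || wi >= W) continue;
            const size_t row0 = (size_t)Ho * (wo + (size_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - ph + ky;
              if (hi < 0 || hi >= H) continue;
              gnc[hi + (size_t)H * wi] += cp[row0 + ho];
            }
          }
        }
      }
    }
  }
  return gx;
}

// Depthwise convolution, weight dim (kh, kw, C) flattened ky fastest.
// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, int H, int W, int N, int C,
                         NumericVector w, NumericVector b,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector y((size_t)Ho * Wo * N * C);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)kh * kw * c;
    const double bc = b[c];
    for (int n = 0; n < N; ++n) {
      const double* xnc = xp + (size_t)H * W * (n + (size_t)N * c);
      double* ync = yp + (size_t)Ho * Wo * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bc;
          for (int kx = 0; kx < kw; ++kx) {
            const int wi = wo * sw - pw + kx;
            if (wi < 0 || wi >= W) continue;
            for (int ky = 0; ky < kh; ++ky) {
              const int hi = ho * sh - ph + ky;
              if (hi < 0 || hi >= H) continue;
              acc += xnc[hi + (size_t)H * wi] * wc[ky + kh * kx];
            }
          }
          ync[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// Backward of the depthwise convolution: returns list(gx, gw, gb).
// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector gy, int H, int W, int N,
                    int C, NumericVector w, int kh, int kw, int sh, int sw,
                    int ph, int pw) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector gx((size_t)H * W * N * C), gw((size_t)kh * kw * C), gb(C);
  const double* xp = x.begin(); const double* gyp = gy.begin();
  const double* wp = w.begin();
  for (int c = 0; c < C; ++c) {
    const double* wc = wp + (size_t)kh * kw * c;
    double* gwc = gw.begin() + (size_t)kh * kw * c;
    double gbc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xnc = xp + (size_t)H * W * (n + (size_t)N * c);
      const double* gync = gyp + (size_t)Ho * Wo * (n + (size_t)N * c);
      double* gxnc = gx.begin() + (size_t)H * W * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gync[ho + (size_t)Ho * wo];
          if (g == 0.0) { continue; }
          gbc += g;
          for (int kx = 0; kx < kw; ++kx) {
            const int wi = wo * sw - pw + kx;
            if (wi < 0 || wi >= W) continue;
            for (int ky = 0; ky < kh; ++ky) {
              const int hi = ho * sh - ph + ky;
              if (hi < 0 || hi >= H) continue;
              gxnc[hi + (size_t)H * wi] += g * wc[ky + kh * kx];
              gwc[ky + kh * kx] += g * xnc[hi + (size_t)H * wi];
            }
          }
        }
      }
    }
    gb[c] = gbc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear resize with the half-pixel (align_corners = FALSE) convention.
// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericVector x, int H, int W, int N, int C,
                           int Ho, int Wo) {
  NumericVector y((size_t)Ho * Wo * N * C);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  std::vector<int> y0(Ho), y1(Ho); std::vector<double> fy(Ho);
  std::vector<int> x0(Wo), x1(Wo); std::vector<double> fx(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sy - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    y0[i] = (int)std::floor(s); y1[i] = std::min(y0[i] + 1, H - 1);
    fy[i] = s - y0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sx - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    x0[j] = (int)std::floor(s); x1[j] = std::min(x0[j] + 1, W - 1);
    fx[j] = s - x0[j];
  }
  const double* xp = x.begin(); double* yp = y.begin();
  const size_t planes = (size_t)N * C;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xs = xp + (size_t)H * W * pl;
    double* ys = yp + (size_t)Ho * Wo * pl;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double a = xs[y0[i] + (size_t)H * x0[j]];
        const double b = xs[y1[i] + (size_t)H * x0[j]];
        const double c2 = xs[y0[i] + (size_t)H * x1[j]];
        const double d = xs[y1[i] + (size_t)H * x1[j]];
        const double top = a + (c2 - a) * fx[j];
        const double bot = b + (d - b) * fx[j];
        ys[i + (size_t)Ho * j] = top + (bot - top) * fy[i];
      }
    }
  }
  return y;
}

// Adjoint of cpp_bilinear.
// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W, int N, int C,
                               int Ho, int Wo) {
  NumericVector gx((size_t)H * W * N * C);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  std::vector<int> y0(Ho), y1(Ho); std::vector<double> fy(Ho);
  std::vector<int> x0(Wo), x1(Wo); std::vector<double> fx(Wo);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sy - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    y0[i] = (int)std::floor(s); y1[i] = std::min(y0[i] + 1, H - 1);
    fy[i] = s - y0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sx - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    x0[j] = (int)std::floor(s); x1[j] = std::min(x0[j] + 1, W - 1);
    fx[j] = s - x0[j];
  }
  const double* gp = gy.begin(); double* xp = gx.begin();
  const size_t planes = (size_t)N * C;
  for (size_t pl = 0; pl < planes; ++pl) {
    double* xs = xp + (size_t)H * W * pl;
    const double* gs = gp + (size_t)Ho * Wo * pl;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = gs[i + (size_t)Ho * j];
        if (g == 0.0) continue;
        const double w00 = (1 - fy[i]) * (1 - fx[j]);
        const double w10 = fy[i] * (1 - fx[j]);
        const double w01 = (1 - fy[i]) * fx[j];
        const double w11 = fy[i] * fx[j];
        xs[y0[i] + (size_t)H * x0[j]] += g * w00;
        xs[y1[i] + (size_t)H * x0[j]] += g * w10;
        xs[y0[i] + (size_t)H * x1[j]] += g * w01;
        xs[y1[i] + (size_t)H * x1[j]] += g * w11;
      }
    }
  }
  return gx;
}

// Fused batch-norm forward: y = x * a[c] + b2[c] over (per x C) layout.
// [[Rcpp::export]]
NumericVector cpp_affine_c(NumericVector x, int per, int C,
                           NumericVector a, NumericVector b2) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b2[c];
    const double* xc = xp + (size_t)per * c;
    double* yc = yp + (size_t)per * c;
    for (int i = 0; i < per; ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}

// Per-channel mean and biased variance over (per x C).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, int per, int C) {
  NumericVector mu(C), va(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)per * c;
    double s = 0, s2 = 0;
    for (int i = 0; i < per; ++i) { s += xc[i]; }
    const double m = s / per;
    for (int i = 0; i < per; ++i) { const double d = xc[i] - m; s2 += d * d; }
    mu[c] = m; va[c] = s2 / per;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// Fused batch-norm backward (training mode).  Returns gx and the
// per-channel gradient sums for gamma and beta.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector g, int per, int C,
                NumericVector mu, NumericVector istd, NumericVector gamma,
                bool batch_stats) {
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  const double* xp = x.begin(); const double* gp = g.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)per * c;
    const double* gc = gp + (size_t)per * c;
    double* gxc = gxp + (size_t)per * c;
    const double m = mu[c], is = istd[c], ga = gamma[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < per; ++i) {
      const double xh = (xc[i] - m) * is;
      sg += gc[i];
      sgx += gc[i] * xh;
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    if (batch_stats) {
      const double msg = sg / per, msgx = sgx / per;
      for (int i = 0; i < per; ++i) {
        const double xh = (xc[i] - m) * is;
        gxc[i] = (gc[i] - msg - xh * msgx) * is * ga;
      }
    } else {
      for (int i = 0; i < per; ++i) gxc[i] = gc[i] * is * ga;
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// Fused SiLU forward and backward.
// [[Rcpp::export]]
NumericVector cpp_silu(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_silu_bwd(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    gx[i] = g[i] * (s + x[i] * s * (1.0 - s));
  }
  return gx;
}
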