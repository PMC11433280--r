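// Low-level tensor kernels for the CNN engine.
//
// Layout conventions (column-major R arrays):
//   activations  x : [H, W, C, N]
//   conv weights w : [kh, kw, Cin/groups, Cout]
//   so the weight memory is exactly a (kh*kw*Cg) x Cout matrix.
// Convolution is im2col + GEMM per image and group; groups = Cin gives a
// depthwise convolution. All kernels are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill `col` ((Ho*Wo) x (kh*kw*Cg)) from image n, channel block [c0, c0+Cg).
static void im2col(const double* x, int H, int W, int C,
                   int n, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& col) {
  const double* xn = x + (size_t)n * H * W * C;
  for (int c = 0; c < Cg; ++c) {
    const double* xc = xn + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        double* colq = col.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kj * dil;
          const bool wok = (iw >= 0 && iw < W);
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + ki * dil;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xc[ih + (size_t)H * iw];
            colq[oh + (size_t)Ho * ow] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of `col` back into dx (inverse access pattern of im2col).
static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int n, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo) {
  double* xn = dx + (size_t)n * H * W * C;
  for (int c = 0; c < Cg; ++c) {
    double* xc = xn + (size_t)(c0 + c) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const double* colq = col.colptr(q);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kj * dil;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + ki * dil;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)H * iw] += colq[oh + (size_t)Ho * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad, int dil, int groups) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cg = dw_[2], Cout = dw_[3];
  if (C != Cg * groups) stop("conv2d: input channels do not match weights/groups");
  const int Coutg = Cout / groups;
  const int Ho = conv_out(H, kh, stride, pad, dil);
  const int Wo = conv_out(W, kw, stride, pad, dil);

  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wmat(w.begin(), (size_t)kh * kw * Cg, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * Cg);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, col);
      arma::mat yg(y.begin() + (size_t)Ho * Wo * (g * Coutg) + (size_t)n * Ho * Wo * Cout,
                   (size_t)Ho * Wo, Coutg, false, true);
      yg = col * wmat.cols(g * Coutg, (g + 1) * Coutg - 1);
      if (bias.size() > 0)
        for (int c = 0; c < Coutg; ++c) yg.col(c) += bias[g * Coutg + c];
    }
  }
  return y;
}

// 1x1 stride-1 convolution: plain per-image GEMM on the raw activation
// memory, no im2col.
// [[Rcpp::export(rng = false)]]
NumericVector conv1x1_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  NumericVector y(Rcpp::no_init((size_t)H * W * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wmat(w.begin(), C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(x.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    arma::mat yn(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout, false, true);
    yn = xn * wmat;
    if (bias.size() > 0)
      for (int c = 0; c < Cout; ++c) yn.col(c) += bias[c];
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List conv1x1_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                     bool has_bias) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  NumericVector dxv(Rcpp::no_init((size_t)H * W * C * N));
  dxv.attr("dim") = dx_;
  NumericVector dwv((size_t)C * Cout);
  dwv.attr("dim") = dw_;
  NumericVector dbv(has_bias ? Cout : 0);
  arma::mat wmat(w.begin(), C, Cout, false, true);
  arma::mat dwmat(dwv.begin(), C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(x.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    arma::mat dyn(dy.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout, false, true);
    arma::mat dxn(dxv.begin() + (size_t)n * H * W * C, (size_t)H * W, C, false, true);
    dwmat += xn.t() * dyn;
    dxn = dyn * wmat.t();
    if (has_bias)
      for (int c = 0; c < Cout; ++c) dbv[c] += arma::accu(dyn.col(c));
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Forward + cached column matrices (groups == 1 fast path): returns the
// output together with the per-image im2col matrices so the backward pass
// need not rebuild them.
// [[Rcpp::export(rng = false)]]
List conv2d_fwd_cache_cpp(NumericVector x, NumericVector w, NumericVector bias,
                          int stride, int pad, int dil) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cg = dw_[2], Cout = dw_[3];
  if (C != Cg) stop("conv2d: input channels do not match weights");
  const int Ho = conv_out(H, kh, stride, pad, dil);
  const int Wo = conv_out(W, kw, stride, pad, dil);

  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  NumericVector colsv(Rcpp::no_init((size_t)Ho * Wo * kh * kw * Cg * N));
  colsv.attr("dim") = IntegerVector::create(Ho * Wo, kh * kw * Cg, N);
  arma::mat wmat(w.begin(), (size_t)kh * kw * Cg, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    arma::mat col(colsv.begin() + (size_t)n * Ho * Wo * kh * kw * Cg,
                  (size_t)Ho * Wo, (size_t)kh * kw * Cg, false, true);
    im2col(x.begin(), H, W, C, n, 0, Cg, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat yg(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    yg = col * wmat;
    if (bias.size() > 0)
      for (int c = 0; c < Cout; ++c) yg.col(c) += bias[c];
  }
  return List::create(_["y"] = y, _["cols"] = colsv);
}

// Backward using cached columns (groups == 1).
// [[Rcpp::export(rng = false)]]
List conv2d_bwd_cache_cpp(NumericVector cols, NumericVector w, NumericVector dy,
                          int H, int W, int stride, int pad, int dil,
                          bool has_bias) {
  IntegerVector dw_ = w.attr("dim"), dd_ = dy.attr("dim");
  const int kh = dw_[0], kw = dw_[1], Cg = dw_[2], Cout = dw_[3];
  const int Ho = dd_[0], Wo = dd_[1], N = dd_[3];

  NumericVector dxv((size_t)H * W * Cg * N);
  dxv.attr("dim") = IntegerVector::create(H, W, Cg, N);
  NumericVector dwv((size_t)kh * kw * Cg * Cout);
  dwv.attr("dim") = dw_;
  NumericVector dbv(has_bias ? Cout : 0);

  arma::mat wmat(w.begin(), (size_t)kh * kw * Cg, Cout, false, true);
  arma::mat dwmat(dwv.begin(), (size_t)kh * kw * Cg, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    arma::mat col(cols.begin() + (size_t)n * Ho * Wo * kh * kw * Cg,
                  (size_t)Ho * Wo, (size_t)kh * kw * Cg, false, true);
    arma::mat dyg(dy.begin() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    dwmat += col.t() * dyg;
    arma::mat dcol = dyg * wmat.t();
    col2im(dcol, dxv.begin(), H, W, Cg, n, 0, Cg, kh, kw, stride, pad, dil, Ho, Wo);
    if (has_bias)
      for (int c = 0; c < Cout; ++c) dbv[c] += arma::accu(dyg.col(c));
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, int groups, bool has_bias,
                    bool need_dx) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim"), dd_ = dy.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cg = dw_[2], Cout = dw_[3];
  const int Ho = dd_[0], Wo = dd_[1];
  const int Coutg = Cout / groups;

  NumericVector dxv((size_t)(need_dx ? (size_t)H * W * C * N : 0));
  if (need_dx) dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((size_t)kh * kw * Cg * Cout);
  dwv.attr("dim") = dw_;
  NumericVector dbv(has_bias ? Cout : 0);

  arma::mat wmat(w.begin(), (size_t)kh * kw * Cg, Cout, false, true);
  arma::mat dwmat(dwv.begin(), (size_t)kh * kw * Cg, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * Cg);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      arma::mat dyg(dy.begin() + (size_t)Ho * Wo * (g * Coutg) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Coutg, false, true);
      im2col(x.begin(), H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, col);
      dwmat.cols(g * Coutg, (g + 1) * Coutg - 1) += col.t() * dyg;
      if (need_dx) {
        arma::mat dcol = dyg * wmat.cols(g * Coutg, (g + 1) * Coutg - 1).t();
        col2im(dcol, dxv.begin(), H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo);
      }
      if (has_bias) {
        for (int c = 0; c < Coutg; ++c)
          dbv[g * Coutg + c] += arma::accu(dyg.col(c));
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Specialised depthwise convolution (groups == C, depth multiplier 1):
// direct loops, no im2col/GEMM overhead.
// [[Rcpp::export(rng = false)]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w,
                               int stride, int pad, int dil) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1];
  const int Ho = conv_out(H, kh, stride, pad, dil);
  const int Wo = conv_out(W, kw, stride, pad, dil);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* yc = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          if (wv == 0.0) continue;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj * dil;
            if (iw < 0 || iw >= W) continue;
            const double* xcol = xc + (size_t)H * iw;
            double* ycol = yc + (size_t)Ho * ow;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + ki * dil;
              if (ih < 0 || ih >= H) continue;
              ycol[oh] += wv * xcol[ih];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad, int dil) {
  IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim"), dd_ = dy.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1];
  const int Ho = dd_[0], Wo = dd_[1];
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = dx_;
  NumericVector dwv((size_t)kh * kw * C);
  dwv.attr("dim") = dw_;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      const double* gc = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      double* dxc = dxv.begin() + ((size_t)n * C + c) * H * W;
      double* dwc = dwv.begin() + (size_t)c * kh * kw;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          double acc = 0.0;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kj * dil;
            if (iw < 0 || iw >= W) continue;
            const double* xcol = xc + (size_t)H * iw;
            double* dxcol = dxc + (size_t)H * iw;
            const double* gcol = gc + (size_t)Ho * ow;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + ki * dil;
              if (ih < 0 || ih >= H) continue;
              const double g = gcol[oh];
              acc += g * xcol[ih];
              dxcol[ih] += g * wv;
            }
          }
          dwc[ki + kh * kj] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv);
}

// Bilinear resize (half-pixel centres, clamped), forward.
// [[Rcpp::export(rng = false)]]
NumericVector resize_bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ha(Ho), wa(Wo);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); ha[i] = s - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); wa[j] = s - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)cn * H * W;
    double* yc = y.begin() + (size_t)cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double a = ha[i], b = wa[j];
        yc[i + (size_t)Ho * j] =
          (1 - a) * (1 - b) * xc[h0[i] + (size_t)H * w0[j]] +
          a       * (1 - b) * xc[h1[i] + (size_t)H * w0[j]] +
          (1 - a) * b       * xc[h0[i] + (size_t)H * w1[j]] +
          a       * b       * xc[h1[i] + (size_t)H * w1[j]];
      }
    }
  }
  return y;
}

// Transpose of the bilinear resize (scatter-add of output gradients).
// [[Rcpp::export(rng = false)]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector dd_ = dy.attr("dim");
  const int Ho = dd_[0], Wo = dd_[1], C = dd_[2], N = dd_[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ha(Ho), wa(Wo);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); ha[i] = s - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); wa[j] = s - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    double* xc = dx.begin() + (size_t)cn * H * W;
    const double* yc = dy.begin() + (size_t)cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = yc[i + (size_t)Ho * j];
        const double a = ha[i], b = wa[j];
        xc[h0[i] + (size_t)H * w0[j]] += (1 - a) * (1 - b) * g;
        xc[h1[i] + (size_t)H * w0[j]] += a       * (1 - b) * g;
        xc[h0[i] + (size_t)H * w1[j]] += (1 - a) * b       * g;
        xc[h1[i] + (size_t)H * w1[j]] += a       * b       * g;
      }
    }
  }
  return dx;
}

// Non-overlapping average pooling by integer factors (area downsampling).
// [[Rcpp::export(rng = false)]]
NumericVector avgpool2d_fwd_cpp(NumericVector x, int fh, int fw) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int Ho = H / fh, Wo = W / fw;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (fh * fw);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)cn * H * W;
    double* yc = y.begin() + (size_t)cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double s = 0;
        for (int b = 0; b < fw; ++b)
          for (int a = 0; a < fh; ++a)
            s += xc[(i * fh + a) + (size_t)H * (j * fw + b)];
        yc[i + (size_t)Ho * j] = s * inv;
      }
  }
  return y;
}

// [[Rcpp::export(rng = false)]]
NumericVector avgpool2d_bwd_cpp(NumericVector dy, int fh, int fw) {
  IntegerVector dd_ = dy.attr("dim");
  const int Ho = dd_[0], Wo = dd_[1], C = dd_[2], N = dd_[3];
  const int H = Ho * fh, W = Wo * fw;
  NumericVector dx(Rcpp::no_init((size_t)H * W * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (fh * fw);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* yc = dy.begin() + (size_t)cn * Ho * Wo;
    double* xc = dx.begin() + (size_t)cn * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = yc[i + (size_t)Ho * j] * inv;
        for (int b = 0; b < fw; ++b)
          for (int a = 0; a < fh; ++a)
            xc[(i * fh + a) + (size_t)H * (j * fw + b)] = g;
      }
  }
  return dx;
}
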