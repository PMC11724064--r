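// Low-level tensor ops for the separable-convolution residual classifier.
//
// Layout convention: activations are dense double arrays with dim
// (C, H, W, N), column-major, i.e. channel-fastest. With this layout a
// 1x1 (pointwise) convolution is a single BLAS gemm on zero-copy views,
// and the (Cout, Ho, Wo, N) output of the generic im2col path is exactly
// the gemm result matrix (Cout x Ho*Wo*N) — no transposition passes.
// Convolution kernels are (kh, kw, Cin, Cout); depthwise kernels are
// (kh, kw, C). Convolutions use TensorFlow-style "same" padding:
// out = ceil(in / stride), pad_begin = pad_total / 2.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void same_pad(int in, int k, int s, int& out, int& pad_beg) {
  out = (in + s - 1) / s;
  int pad_total = std::max((out - 1) * s + k - in, 0);
  pad_beg = pad_total / 2;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (C,H,W,N) array");
  return d;
}

// col is (K x M) with K = kh*kw*C (index i + kh*(j + kw*c), matching the
// column-major flattening of a (kh, kw, C) kernel) and M = Ho*Wo*N
// (index ho + Ho*(wo + Wo*n), matching the (Cout, Ho, Wo, N) output).
static void im2col(const double* x, int C, int H, int W, int N,
                   int kh, int kw, int stride,
                   int Ho, int Wo, int ph, int pw, arma::mat& col) {
  const int K = kh * kw * C;
  col.set_size(K, (arma::uword)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* cm = col.colptr((arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n));
        int h0 = ho * stride - ph, w0 = wo * stride - pw;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          bool wok = wi >= 0 && wi < W;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (wok && hi >= 0 && hi < H) {
              const double* xs = xn + (size_t)C * (hi + (size_t)H * wi);
              for (int c = 0; c < C; ++c) cm[i + kh * (j + kw * c)] = xs[c];
            } else {
              for (int c = 0; c < C; ++c) cm[i + kh * (j + kw * c)] = 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* dx,
                       int C, int H, int W, int N,
                       int kh, int kw, int stride,
                       int Ho, int Wo, int ph, int pw) {
  for (int n = 0; n < N; ++n) {
    double* dxn = dx + (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* cm = col.colptr((arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n));
        int h0 = ho * stride - ph, w0 = wo * stride - pw;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            double* xs = dxn + (size_t)C * (hi + (size_t)H * wi);
            for (int c = 0; c < C; ++c) xs[c] += cm[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b, int stride) {
  IntegerVector xd = dims4(x), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int Ho, Wo, ph, pw;
  same_pad(H, kh, stride, Ho, ph);
  same_pad(W, kw, stride, Wo, pw);
  arma::uword M = (arma::uword)Ho * Wo * N;
  NumericVector out((R_xlen_t)Cout * M);
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * Cin, Cout, false, true);
  arma::mat Y(out.begin(), Cout, M, false, true);
  if (kh == 1 && kw == 1 && stride == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, M, false, true);
    Y = Wm.t() * X;
  } else {
    arma::mat col;
    im2col(x.begin(), C, H, W, N, kh, kw, stride, Ho, Wo, ph, pw, col);
    Y = Wm.t() * col;
  }
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  Y.each_col() += bv;
  return out;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(const NumericVector& x, const NumericVector& w,
                   const NumericVector& dy, int stride) {
  IntegerVector xd = dims4(x), wd = w.attr("dim"), yd = dims4(dy);
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[1], Wo = yd[2];
  int Ho2, Wo2, ph, pw;
  same_pad(H, kh, stride, Ho2, ph);
  same_pad(W, kw, stride, Wo2, pw);
  arma::uword M = (arma::uword)Ho * Wo * N;
  arma::mat dY(const_cast<double*>(dy.begin()), Cout, M, false, true);
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)kh * kw * C, Cout, false, true);
  NumericVector dx((R_xlen_t)C * H * W * N);
  dx.attr("dim") = xd;
  arma::mat dW;
  if (kh == 1 && kw == 1 && stride == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, M, false, true);
    dW = X * dY.t();
    arma::mat DX(dx.begin(), C, M, false, true);
    DX = Wm * dY;
  } else {
    arma::mat col;
    im2col(x.begin(), C, H, W, N, kh, kw, stride, Ho, Wo, ph, pw, col);
    dW = col * dY.t();
    arma::mat dcol = Wm * dY;
    col2im_add(dcol, dx.begin(), C, H, W, N, kh, kw, stride, Ho, Wo, ph, pw);
  }
  arma::vec db = arma::sum(dY, 1);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Depthwise kh x kw convolution, stride 1, same padding. The channel-fastest
// layout makes the inner loop a contiguous vector op over C.
// [[Rcpp::export]]
NumericVector nn_dwconv_fwd(const NumericVector& x, const NumericVector& w) {
  IntegerVector xd = dims4(x), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector out((R_xlen_t)C * H * W * N);
  out.attr("dim") = xd;
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  std::vector<double> wt(C);
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) wt[c] = wp[i + kh * (j + kw * c)];
      int dh = i - ph, dw_ = j - pw;
      for (int n = 0; n < N; ++n) {
        const double* xn = xp + (size_t)C * H * W * n;
        double* on = op + (size_t)C * H * W * n;
        int wlo = std::max(0, -dw_), whi = std::min(W, W - dw_);
        int hlo = std::max(0, -dh), hhi = std::min(H, H - dh);
        for (int wo = wlo; wo < whi; ++wo) {
          for (int ho = hlo; ho < hhi; ++ho) {
            const double* xs = xn + (size_t)C * ((ho + dh) + (size_t)H * (wo + dw_));
            double* os = on + (size_t)C * (ho + (size_t)H * wo);
            for (int c = 0; c < C; ++c) os[c] += wt[c] * xs[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List nn_dwconv_bwd(const NumericVector& x, const NumericVector& w,
                   const NumericVector& dy) {
  IntegerVector xd = dims4(x), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dx((R_xlen_t)C * H * W * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)kh * kw * C);
  dw.attr("dim") = wd;
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  std::vector<double> wt(C), dwt(C);
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int c = 0; c < C; ++c) wt[c] = wp[i + kh * (j + kw * c)];
      std::fill(dwt.begin(), dwt.end(), 0.0);
      int dh = i - ph, dw_ = j - pw;
      for (int n = 0; n < N; ++n) {
        const double* xn = xp + (size_t)C * H * W * n;
        const double* gn = dyp + (size_t)C * H * W * n;
        double* dxn = dxp + (size_t)C * H * W * n;
        int wlo = std::max(0, -dw_), whi = std::min(W, W - dw_);
        int hlo = std::max(0, -dh), hhi = std::min(H, H - dh);
        for (int wo = wlo; wo < whi; ++wo) {
          for (int ho = hlo; ho < hhi; ++ho) {
            size_t si = (size_t)C * ((ho + dh) + (size_t)H * (wo + dw_));
            size_t oi = (size_t)C * (ho + (size_t)H * wo);
            const double* xs = xn + si;
            const double* gs = gn + oi;
            double* dxs = dxn + si;
            for (int c = 0; c < C; ++c) {
              dxs[c] += wt[c] * gs[c];
              dwt[c] += gs[c] * xs[c];
            }
          }
        }
      }
      for (int c = 0; c < C; ++c) dwp[i + kh * (j + kw * c)] = dwt[c];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Batch normalisation over (H, W, N) per channel.
// [[Rcpp::export]]
List nn_bn_fwd(const NumericVector& x, const NumericVector& gamma,
               const NumericVector& beta, const NumericVector& rmean,
               const NumericVector& rvar, double momentum, double eps,
               bool training) {
  IntegerVector xd = dims4(x);
  int C = xd[0];
  R_xlen_t P = (R_xlen_t)xd[1] * xd[2] * xd[3]; // spatial*batch positions
  NumericVector y((R_xlen_t)C * P);
  y.attr("dim") = xd;
  NumericVector mean(C), var(C), nrm(C), nrv(C);
  const double* xp = x.begin();
  if (training) {
    std::vector<double> s(C, 0.0), s2(C, 0.0);
    for (R_xlen_t p = 0; p < P; ++p) {
      const double* xs = xp + (size_t)C * p;
      for (int c = 0; c < C; ++c) {
        s[c] += xs[c];
        s2[c] += xs[c] * xs[c];
      }
    }
    for (int c = 0; c < C; ++c) {
      double m = s[c] / P;
      double v = s2[c] / P - m * m;
      if (v < 0) v = 0;
      mean[c] = m;
      var[c] = v;
      nrm[c] = momentum * rmean[c] + (1 - momentum) * m;
      nrv[c] = momentum * rvar[c] + (1 - momentum) * v;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mean[c] = rmean[c];
      var[c] = rvar[c];
    }
    nrm = clone(rmean);
    nrv = clone(rvar);
  }
  std::vector<double> scale(C), shift(C);
  for (int c = 0; c < C; ++c) {
    scale[c] = gamma[c] / std::sqrt(var[c] + eps);
    shift[c] = beta[c] - mean[c] * scale[c];
  }
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* xs = xp + (size_t)C * p;
    double* ys = yp + (size_t)C * p;
    for (int c = 0; c < C; ++c) ys[c] = xs[c] * scale[c] + shift[c];
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List nn_bn_bwd(const NumericVector& x, const NumericVector& gamma,
               const NumericVector& mean, const NumericVector& var,
               double eps, const NumericVector& dy) {
  IntegerVector xd = dims4(x);
  int C = xd[0];
  R_xlen_t P = (R_xlen_t)xd[1] * xd[2] * xd[3];
  NumericVector dx((R_xlen_t)C * P);
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  std::vector<double> istd(C), sdy(C, 0.0), sdyx(C, 0.0);
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(var[c] + eps);
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* xs = xp + (size_t)C * p;
    const double* gs = dyp + (size_t)C * p;
    for (int c = 0; c < C; ++c) {
      sdy[c] += gs[c];
      sdyx[c] += gs[c] * (xs[c] - mean[c]) * istd[c];
    }
  }
  std::vector<double> k(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sdyx[c];
    dbeta[c] = sdy[c];
    k[c] = gamma[c] * istd[c] / P;
  }
  for (R_xlen_t p = 0; p < P; ++p) {
    const double* xs = xp + (size_t)C * p;
    const double* gs = dyp + (size_t)C * p;
    double* dxs = dxp + (size_t)C * p;
    for (int c = 0; c < C; ++c) {
      double xh = (xs[c] - mean[c]) * istd[c];
      dxs[c] = k[c] * (P * gs[c] - sdy[c] - xh * sdyx[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling, TF "same" padding; records 0-based argmax into the input.
// [[Rcpp::export]]
List nn_maxpool_fwd(const NumericVector& x, int k, int stride) {
  IntegerVector xd = dims4(x);
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Ho, Wo, ph, pw;
  same_pad(H, k, stride, Ho, ph);
  same_pad(W, k, stride, Wo, pw);
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  IntegerVector amax((R_xlen_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    size_t nbase = (size_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* ys = yp + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
        int* as = ap + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
        for (int c = 0; c < C; ++c) {
          ys[c] = -std::numeric_limits<double>::infinity();
          as[c] = -1;
        }
        for (int j = 0; j < k; ++j) {
          int wi = wo * stride - pw + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            int hi = ho * stride - ph + i;
            if (hi < 0 || hi >= H) continue;
            const double* xs = xn + (size_t)C * (hi + (size_t)H * wi);
            size_t sbase = nbase + (size_t)C * (hi + (size_t)H * wi);
            for (int c = 0; c < C; ++c) {
              if (xs[c] > ys[c]) {
                ys[c] = xs[c];
                as[c] = (int)(sbase + c);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(const NumericVector& dy, const IntegerVector& amax,
                             const IntegerVector& xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = amax.begin();
  R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ap[i]] += dyp[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_relu_fwd(const NumericVector& x) {
  NumericVector y = clone(x);
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    if (yp[i] < 0) yp[i] = 0;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd(const NumericVector& x, const NumericVector& dy) {
  NumericVector dx = clone(dy);
  double* dxp = dx.begin();
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) {
    if (xp[i] <= 0) dxp[i] = 0;
  }
  return dx;
}

// Global average pooling over (H, W): (C, H, W, N) -> (C, N).
// [[Rcpp::export]]
NumericMatrix nn_gap_fwd(const NumericVector& x) {
  IntegerVector xd = dims4(x);
  int C = xd[0], N = xd[3];
  R_xlen_t S = (R_xlen_t)xd[1] * xd[2]; // spatial positions per sample
  NumericMatrix out(C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    double* os = &out(0, n);
    const double* xn = xp + (size_t)C * S * n;
    for (R_xlen_t p = 0; p < S; ++p) {
      const double* xs = xn + (size_t)C * p;
      for (int c = 0; c < C; ++c) os[c] += xs[c];
    }
    for (int c = 0; c < C; ++c) os[c] /= S;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_gap_bwd(const NumericMatrix& dg, const IntegerVector& xdim) {
  int C = xdim[0], N = xdim[3];
  R_xlen_t S = (R_xlen_t)xdim[1] * xdim[2];
  NumericVector dx((R_xlen_t)C * S * N);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double* gs = &dg(0, n);
    double* dxn = dxp + (size_t)C * S * n;
    for (R_xlen_t p = 0; p < S; ++p) {
      double* dxs = dxn + (size_t)C * p;
      for (int c = 0; c < C; ++c) dxs[c] = gs[c] / S;
    }
  }
  return dx;
}

// Bilinear resize of one (H, W, C) image, half-pixel centre alignment.
// (Tile rasters keep the image-layout convention; stacking into the
// channel-fastest training layout happens after the resize.)
// [[Rcpp::export]]
NumericVector nn_resize_bilinear(const NumericVector& x, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("expected a (H,W,C) array");
  int H = xd[0], W = xd[1], C = xd[2];
  NumericVector out((R_xlen_t)oh * ow * C);
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double* xp = x.begin();
  double* op = out.begin();
  double sh = (double)H / oh, sw = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* oc = op + (size_t)c * oh * ow;
    for (int wo = 0; wo < ow; ++wo) {
      double fx = (wo + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(fx);
      double tx = fx - x0;
      int x1 = x0 + 1;
      x0 = std::min(std::max(x0, 0), W - 1);
      x1 = std::min(std::max(x1, 0), W - 1);
      for (int ho = 0; ho < oh; ++ho) {
        double fy = (ho + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(fy);
        double ty = fy - y0;
        int y1 = y0 + 1;
        y0 = std::min(std::max(y0, 0), H - 1);
        y1 = std::min(std::max(y1, 0), H - 1);
        double v = (1 - ty) * ((1 - tx) * xc[y0 + (size_t)H * x0] + tx * xc[y0 + (size_t)H * x1]) +
                   ty * ((1 - tx) * xc[y1 + (size_t)H * x0] + tx * xc[y1 + (size_t)H * x1]);
        oc[ho + (size_t)oh * wo] = v;
      }
    }
  }
  return out;
}
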