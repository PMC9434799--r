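// Convolution / pooling kernels for the segmentation network.
// Array layout follows R's column-major convention throughout:
//   feature maps  x : (H, W, C, N)
//   conv weights  w : (kh, kw, Cin, Cout)
//   deconv weights (2x2, stride 2) share the same layout.
// Stride-1 dilated convolutions use im2col + BLAS gemm; the transposed
// convolution and max pooling are direct scatter/gather loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uvec dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return arma::uvec{(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]};
}

// Build the im2col matrix K (kh*kw*Cin x H*W) for one image (same-size output).
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int dil, int pad, arma::mat &K) {
  int q = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i, ++q) {
      double *col = K.colptr(q);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double *xc = x + (size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          int jj = j + dil * b - pad;
          for (int a = 0; a < kh; ++a, ++r) {
            int ii = i + dil * a - pad;
            col[r] = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? xc[ii + (size_t)jj * H] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back onto the (H, W, C) image grid.
static void col2im(const arma::mat &K, int H, int W, int C,
                   int kh, int kw, int dil, int pad, double *gx) {
  int q = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i, ++q) {
      const double *col = K.colptr(q);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double *gc = gx + (size_t)c * H * W;
        for (int b = 0; b < kw; ++b) {
          int jj = j + dil * b - pad;
          for (int a = 0; a < kh; ++a, ++r) {
            int ii = i + dil * a - pad;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W) gc[ii + (size_t)jj * H] += col[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                            int dil, int pad) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  if ((int)dw[2] != C) stop("conv2d: input has %d channels but weights expect %d", C, (int)dw[2]);
  int R = kh * kw * C, HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector y((size_t)HW * Cout * N);
  arma::mat K(R, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, dil, pad, K);
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = K.t() * Wm;  // (HW x Cout)
    Y.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), Cout, false, true);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int dil, int pad) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  int R = kh * kw * C, HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector gx((size_t)HW * C * N), gw(w.size()), gb(Cout);
  arma::mat GW(gw.begin(), R, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat K(R, HW);
  for (int n = 0; n < N; ++n) {
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * HW * Cout, HW, Cout, false, true);
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, dil, pad, K);
    GW += K * GY;
    GB += arma::sum(GY, 0).t();
    arma::mat Gcol = Wm * GY.t();           // (R x HW)
    col2im(Gcol, H, W, C, kh, kw, dil, pad, gx.begin() + (size_t)n * HW * C);
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution (the decoder upsampling).
// [[Rcpp::export(name = ".cpp_convt2d_fw")]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector bias) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3];
  if ((int)dw[2] != C) stop("convt2d: channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  // weight as (4*Cin) x Cout with rows ordered (a, b, ci)
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C, H * W, C, false, true);
    for (int co = 0; co < Cout; ++co) {
      double *yc = y.begin() + ((size_t)n * Cout + co) * Ho * Wo;
      for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
        // y[2i+a, 2j+b, co] = sum_ci x[i,j,ci] * w[a,b,ci,co] + bias
        for (int ci = 0; ci < C; ++ci) {
          double wv = Wm(a + 2 * b + 4 * ci, co);
          if (wv == 0.0) continue;
          const double *xc = X.colptr(ci);
          for (int j = 0; j < W; ++j) {
            double *ycol = yc + (size_t)(2 * j + b) * Ho + a;
            const double *xcol = xc + (size_t)j * H;
            for (int i = 0; i < H; ++i) ycol[2 * i] += wv * xcol[i];
          }
        }
      }
      double bv = bias[co];
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) yc[t] += bv;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".cpp_convt2d_bw")]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  arma::uvec dx = dims4(x), dw = dims4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Cout = dw[3], Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * C, Cout, false, true);
  arma::mat GW(gw.begin(), 4 * C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *gyc = gy.begin() + ((size_t)n * Cout + co) * Ho * Wo;
      double s = 0.0;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) s += gyc[t];
      gb[co] += s;
      for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
        for (int ci = 0; ci < C; ++ci) {
          const double *xc = x.begin() + ((size_t)n * C + ci) * H * W;
          double *gxc = gx.begin() + ((size_t)n * C + ci) * H * W;
          double wv = Wm(a + 2 * b + 4 * ci, co), acc = 0.0;
          for (int j = 0; j < W; ++j) {
            const double *gcol = gyc + (size_t)(2 * j + b) * Ho + a;
            const double *xcol = xc + (size_t)j * H;
            double *gxcol = gxc + (size_t)j * H;
            for (int i = 0; i < H; ++i) {
              double g = gcol[2 * i];
              acc += g * xcol[i];
              gxcol[i] += g * wv;
            }
          }
          GW(a + 2 * b + 4 * ci, co) += acc;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(2, 2, C, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; returns pooled values and argmax linear indices.
// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x) {
  arma::uvec dx = dims4(x);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + ((size_t)n * C + c) * H * W;
    size_t base = ((size_t)n * C + c) * H * W;
    for (int j = 0; j < Wo; ++j) for (int i = 0; i < Ho; ++i, ++q) {
      double best = -INFINITY; size_t bi = 0;
      for (int b = 0; b < 2; ++b) for (int a = 0; a < 2; ++a) {
        size_t t = (size_t)(2 * i + a) + (size_t)(2 * j + b) * H;
        if (xc[t] > best) { best = xc[t]; bi = base + t; }
      }
      // column-major fill only matches when iterating i fastest; recompute index
      size_t out_t = (size_t)i + (size_t)j * Ho + ((size_t)n * C + c) * Ho * Wo;
      y[out_t] = best; idx[out_t] = (int)bi;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy, IntegerVector dim_in) {
  size_t n = (size_t)dim_in[0] * dim_in[1] * dim_in[2] * dim_in[3];
  NumericVector gx(n);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  gx.attr("dim") = dim_in;
  return gx;
}
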