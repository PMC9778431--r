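// Convolution primitives for the segmentation network.
// Tensor layout is the R column-major array (H, W, C, N); weights are
// (kh, kw, Cin, Cout).  im2col produces a (kh*kw*Cin) x (OH*OW) matrix per
// sample so both directions reduce to GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int OH, int OW, arma::mat& M) {
  // M: (kh*kw*C) x (OH*OW); column j = oh + OH*ow
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wj = ow * sw - pw + kj * dw;
          bool wok = (wj >= 0 && wj < W);
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * sh - ph + ki * dh;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wj];
            M(row, oh + OH * ow) = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& M, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int OH, int OW, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wj = ow * sw - pw + kj * dw;
          if (wj < 0 || wj >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * sh - ph + ki * dh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wj] += M(row, oh + OH * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, bool has_bias,
                             int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int OH = out_extent(H, kh, sh, ph, dh);
  int OW = out_extent(W, kw, sw, pw, dw);
  if (OH < 1 || OW < 1) stop("conv2d: output would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector out((size_t)OH * OW * Cout * N);
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  arma::mat M(kh * kw * Cin, (size_t)OH * OW);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col(xn, H, W, C, kh, kw, sh, sw, ph, pw, dh, dw, OH, OW, M);
    arma::mat Y = Wm.t() * M;  // Cout x (OH*OW)
    double* on = out.begin() + (size_t)n * OH * OW * Cout;
    for (int c = 0; c < Cout; ++c) {
      double bc = has_bias ? bias[c] : 0.0;
      double* oc = on + (size_t)c * OH * OW;
      for (size_t j = 0; j < (size_t)OH * OW; ++j) oc[j] = Y(c, j) + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    bool has_bias,
                    int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int OH = gd[0], OW = gd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat gW(kh * kw * C, Cout, arma::fill::zeros);
  arma::vec gB(Cout, arma::fill::zeros);
  arma::mat M(kh * kw * C, (size_t)OH * OW);
  arma::mat GY(Cout, (size_t)OH * OW);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* gn = gy.begin() + (size_t)n * OH * OW * Cout;
    for (int c = 0; c < Cout; ++c)
      for (size_t j = 0; j < (size_t)OH * OW; ++j)
        GY(c, j) = gn[j + (size_t)c * OH * OW];
    im2col(xn, H, W, C, kh, kw, sh, sw, ph, pw, dh, dw, OH, OW, M);
    gW += M * GY.t();
    if (has_bias) gB += arma::sum(GY, 1);
    arma::mat Gcol = Wm * GY;  // (kh*kw*C) x (OH*OW)
    col2im(Gcol, H, W, C, kh, kw, sh, sw, ph, pw, dh, dw, OH, OW,
           gx.begin() + (size_t)n * H * W * C);
  }

  NumericVector gWout(wd[0] * wd[1] * wd[2] * wd[3]);
  std::copy(gW.begin(), gW.end(), gWout.begin());
  gWout.attr("dim") = wd;
  NumericVector gBout(Cout);
  std::copy(gB.begin(), gB.end(), gBout.begin());
  return List::create(_["gx"] = gx, _["gw"] = gWout, _["gb"] = gBout);
}
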