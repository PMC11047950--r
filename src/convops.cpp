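#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2D convolution on [H, W, C, N] column-major arrays via im2col + GEMM.
// Weights are [kh, kw, Cin, Cout]; zero padding `pad`, square stride
// `stride`. Loops are ordered so that both the patch matrix and the
// source array are walked contiguously along the image-row dimension.

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (kh*kw*Cin x Ho*Wo) for image n of x.
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* cp = cols.colptr(ho + Ho * wo);
      int h0 = ho * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride - pad + kj;
          double* dst = cp + kh * (kj + kw * c);
          if (wi < 0 || wi >= W) {
            for (int ki = 0; ki < kh; ++ki) dst[ki] = 0.0;
          } else {
            const double* src = xn + (size_t)H * (wi + (size_t)W * c);
            for (int ki = 0; ki < kh; ++ki) {
              int hi = h0 + ki;
              dst[ki] = (hi >= 0 && hi < H) ? src[hi] : 0.0;
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back to image n of dx (adjoint of im2col).
static void col2im(const arma::mat& cols, double* dx, int H, int W, int C,
                   int n, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  double* xn = dx + (size_t)H * W * C * n;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* cp = cols.colptr(ho + Ho * wo);
      int h0 = ho * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* src = cp + kh * (kj + kw * c);
          double* dst = xn + (size_t)H * (wi + (size_t)W * c);
          for (int ki = 0; ki < kh; ++ki) {
            int hi = h0 + ki;
            if (hi >= 0 && hi < H) dst[hi] += src[ki];
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w, int kh, int kw,
                               int Cin, int Cout) {
  arma::mat Wm(Cout, kh * kw * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int r = 0; r < kh * kw * Cin; ++r)
      Wm(o, r) = w[r + (size_t)kh * kw * Cin * o];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, bool relu) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(kh * kw * Cin, Ho * Wo);
  const int P = Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x), H, W, C, n, kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat yn = Wm * cols;  // Cout x P
    double* yp = REAL(y) + (size_t)P * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      double bo = b[o];
      double* dst = yp + (size_t)P * o;
      const double* src = yn.memptr() + o;  // row o, stride Cout
      if (relu) {
        for (int p = 0; p < P; ++p) {
          double v = src[(size_t)p * Cout] + bo;
          dst[p] = v > 0 ? v : 0.0;
        }
      } else {
        for (int p = 0; p < P; ++p) dst[p] = src[(size_t)p * Cout] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector pre) {
  NumericVector d(dy.size());
  d.attr("dim") = dy.attr("dim");
  const double* dp = REAL(dy);
  const double* pp = REAL(pre);
  double* op = REAL(d);
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = pp[i] > 0 ? dp[i] : 0.0;
  return d;
}

// Backward pass. If `post` is non-empty it holds the ReLU output of this
// convolution and dy is masked by post > 0 while it is gathered (fused
// ReLU backward).
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool want_dx,
                    NumericVector post) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  const int P = Ho * Wo;
  const bool mask = post.size() > 0;

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  NumericVector dx(want_dx ? (size_t)H * W * C * N : 0);
  if (want_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dWm(Cout, kh * kw * Cin, arma::fill::zeros);
  NumericVector db(Cout);
  arma::mat cols(kh * kw * Cin, P);
  arma::mat dyn(Cout, P);

  for (int n = 0; n < N; ++n) {
    const double* dyp = REAL(dy) + (size_t)P * Cout * n;
    const double* pp = mask ? REAL(post) + (size_t)P * Cout * n : nullptr;
    for (int o = 0; o < Cout; ++o) {
      const double* src = dyp + (size_t)P * o;
      const double* ps = mask ? pp + (size_t)P * o : nullptr;
      double* dst = dyn.memptr() + o;
      double acc = 0.0;
      for (int p = 0; p < P; ++p) {
        double v = src[p];
        if (mask && ps[p] <= 0) v = 0.0;
        dst[(size_t)p * Cout] = v;
        acc += v;
      }
      db[o] += acc;
    }
    im2col(REAL(x), H, W, C, n, kh, kw, stride, pad, Ho, Wo, cols);
    dWm += dyn * cols.t();
    if (want_dx) {
      arma::mat dcols = Wm.t() * dyn;
      col2im(dcols, REAL(dx), H, W, C, n, kh, kw, stride, pad, Ho, Wo);
    }
  }

  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int r = 0; r < kh * kw * Cin; ++r)
      dw[r + (size_t)kh * kw * Cin * o] = dWm(o, r);

  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
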