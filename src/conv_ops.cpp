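// Convolution kernels for the segmentation network.
// Tensor layout matches the R side: [H, W, B, C], column-major, so the
// first index varies fastest. Weights for the full convolution are
// [k*k*Cin, Cout] with rows blocked per kernel tap (tap index t = ki +
// k*kj, kernel-row fastest) and channel-within-tap; depthwise weights are
// [k*k, C]. All outputs are freshly allocated; nothing is modified in
// place. The axpy/dot helpers carry __restrict__ and a compile-time-ish
// stride split so the hot loops vectorize.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride) {
  return (n - k) / stride + 1;
}

static inline void axpy1(int n, double a, const double* __restrict x,
                         double* __restrict y) {
  for (int i = 0; i < n; ++i) y[i] += a * x[i];
}

static inline void axpy_s(int n, double a, const double* __restrict x, int sx,
                          double* __restrict y) {
  for (int i = 0; i < n; ++i) y[i] += a * x[i * sx];
}

// y[i*sx] += a * x[i]  (scatter with stride on the output side)
static inline void axpy_sy(int n, double a, const double* __restrict x,
                           double* __restrict y, int sy) {
  for (int i = 0; i < n; ++i) y[i * sy] += a * x[i];
}

static inline double dot1(int n, const double* __restrict x,
                          const double* __restrict y) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i] * y[i];
  return s;
}

static inline double dot_s(int n, const double* __restrict x, int sx,
                           const double* __restrict y) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i * sx] * y[i];
  return s;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericVector conv_fwd_cpp(NumericVector xp, NumericMatrix W,
                           NumericVector bias, int k, int stride) {
  IntegerVector d = xp.attr("dim");
  const int Hp = d[0], Wp = d[1], B = d[2], C = d[3];
  const int Ho = out_len(Hp, k, stride), Wo = out_len(Wp, k, stride);
  const int Cout = W.ncol();
  NumericVector y((R_xlen_t)Ho * Wo * B * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, B, Cout);
  const double *x = xp.begin();
  double *yy = y.begin();
  const R_xlen_t planeX = (R_xlen_t)Hp * Wp;
  const R_xlen_t planeY = (R_xlen_t)Ho * Wo;
  for (int co = 0; co < Cout; ++co) {
    const double *wcol = &W(0, co);
    for (int b = 0; b < B; ++b) {
      double *yb = yy + ((R_xlen_t)co * B + b) * planeY;
      const double bv = bias[co];
      for (R_xlen_t i = 0; i < planeY; ++i) yb[i] = bv;
      for (int c = 0; c < C; ++c) {
        const double *xb = x + ((R_xlen_t)c * B + b) * planeX;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const double w = wcol[(ki + k * kj) * C + c];
            if (w == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const double *xcol = xb + (R_xlen_t)(wo * stride + kj) * Hp + ki;
              double *ycol = yb + (R_xlen_t)wo * Ho;
              if (stride == 1) axpy1(Ho, w, xcol, ycol);
              else axpy_s(Ho, w, xcol, stride, ycol);
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector xp, NumericVector dy, NumericMatrix W,
                  int k, int stride) {
  IntegerVector d = xp.attr("dim");
  const int Hp = d[0], Wp = d[1], B = d[2], C = d[3];
  const int Ho = out_len(Hp, k, stride), Wo = out_len(Wp, k, stride);
  const int Cout = W.ncol();
  NumericVector dxp((R_xlen_t)Hp * Wp * B * C);
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, B, C);
  NumericMatrix dW(W.nrow(), Cout);
  NumericVector db(Cout);
  const double *x = xp.begin();
  const double *g = dy.begin();
  double *dx = dxp.begin();
  const R_xlen_t planeX = (R_xlen_t)Hp * Wp;
  const R_xlen_t planeY = (R_xlen_t)Ho * Wo;
  for (int co = 0; co < Cout; ++co) {
    const double *wcol = &W(0, co);
    double *dwcol = &dW(0, co);
    double dbacc = 0.0;
    for (int b = 0; b < B; ++b) {
      const double *gb = g + ((R_xlen_t)co * B + b) * planeY;
      for (R_xlen_t i = 0; i < planeY; ++i) dbacc += gb[i];
      for (int c = 0; c < C; ++c) {
        const double *xb = x + ((R_xlen_t)c * B + b) * planeX;
        double *dxb = dx + ((R_xlen_t)c * B + b) * planeX;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int r = (ki + k * kj) * C + c;
            const double w = wcol[r];
            double dwacc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const R_xlen_t xoff = (R_xlen_t)(wo * stride + kj) * Hp + ki;
              const double *gcol = gb + (R_xlen_t)wo * Ho;
              if (stride == 1) {
                dwacc += dot1(Ho, xb + xoff, gcol);
                axpy1(Ho, w, gcol, dxb + xoff);
              } else {
                dwacc += dot_s(Ho, xb + xoff, stride, gcol);
                axpy_sy(Ho, w, gcol, dxb + xoff, stride);
              }
            }
            dwcol[r] += dwacc;
          }
        }
      }
    }
    db[co] = dbacc;
  }
  return List::create(_["dxp"] = dxp, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".dwconv_fwd_cpp")]]
NumericVector dwconv_fwd_cpp(NumericVector xp, NumericMatrix W,
                             NumericVector bias, int k, int stride) {
  IntegerVector d = xp.attr("dim");
  const int Hp = d[0], Wp = d[1], B = d[2], C = d[3];
  const int Ho = out_len(Hp, k, stride), Wo = out_len(Wp, k, stride);
  NumericVector y((R_xlen_t)Ho * Wo * B * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  const double *x = xp.begin();
  double *yy = y.begin();
  const R_xlen_t planeX = (R_xlen_t)Hp * Wp;
  const R_xlen_t planeY = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const double *xb = x + ((R_xlen_t)c * B + b) * planeX;
      double *yb = yy + ((R_xlen_t)c * B + b) * planeY;
      const double bv = bias[c];
      for (R_xlen_t i = 0; i < planeY; ++i) yb[i] = bv;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double w = W(ki + k * kj, c);
          if (w == 0.0) continue;
          for (int wo = 0; wo < Wo; ++wo) {
            const double *xcol = xb + (R_xlen_t)(wo * stride + kj) * Hp + ki;
            double *ycol = yb + (R_xlen_t)wo * Ho;
            if (stride == 1) axpy1(Ho, w, xcol, ycol);
            else axpy_s(Ho, w, xcol, stride, ycol);
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dwconv_bwd_cpp")]]
List dwconv_bwd_cpp(NumericVector xp, NumericVector dy, NumericMatrix W,
                    int k, int stride) {
  IntegerVector d = xp.attr("dim");
  const int Hp = d[0], Wp = d[1], B = d[2], C = d[3];
  const int Ho = out_len(Hp, k, stride), Wo = out_len(Wp, k, stride);
  NumericVector dxp((R_xlen_t)Hp * Wp * B * C);
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, B, C);
  NumericMatrix dW(k * k, C);
  NumericVector db(C);
  const double *x = xp.begin();
  const double *g = dy.begin();
  double *dx = dxp.begin();
  const R_xlen_t planeX = (R_xlen_t)Hp * Wp;
  const R_xlen_t planeY = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double dbacc = 0.0;
    for (int b = 0; b < B; ++b) {
      const double *xb = x + ((R_xlen_t)c * B + b) * planeX;
      double *dxb = dx + ((R_xlen_t)c * B + b) * planeX;
      const double *gb = g + ((R_xlen_t)c * B + b) * planeY;
      for (R_xlen_t i = 0; i < planeY; ++i) dbacc += gb[i];
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double w = W(ki + k * kj, c);
          double dwacc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            const R_xlen_t xoff = (R_xlen_t)(wo * stride + kj) * Hp + ki;
            const double *gcol = gb + (R_xlen_t)wo * Ho;
            if (stride == 1) {
              dwacc += dot1(Ho, xb + xoff, gcol);
              axpy1(Ho, w, gcol, dxb + xoff);
            } else {
              dwacc += dot_s(Ho, xb + xoff, stride, gcol);
              axpy_sy(Ho, w, gcol, dxb + xoff, stride);
            }
          }
          dW(ki + k * kj, c) += dwacc;
        }
      }
    }
    db[c] = dbacc;
  }
  return List::create(_["dxp"] = dxp, _["dW"] = dW, _["db"] = db);
}
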