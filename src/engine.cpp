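// Compact CNN engine: conv2d forward/backward via im2col + GEMM.
// Feature maps are R arrays of dim (C, H, W), which map onto arma::cube
// with n_rows = C, n_cols = H, n_slices = W (identical column-major layout).
// Conv weights are matrices of dim (Cout, Cin*kh*kw); the column ordering is
// c + Cin*(ki + kh*kj) for input channel c and kernel offset (ki, kj).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube &x, int kh, int kw, int stride, int pad,
                  int Hout, int Wout) {
  const int C = x.n_rows, H = x.n_cols, W = x.n_slices;
  mat K(C * kh * kw, Hout * Wout, fill::zeros);
  for (int j = 0; j < Wout; ++j) {
    for (int i = 0; i < Hout; ++i) {
      const int p = i + Hout * j;
      for (int kj = 0; kj < kw; ++kj) {
        const int sj = j * stride - pad + kj;
        if (sj < 0 || sj >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int si = i * stride - pad + ki;
          if (si < 0 || si >= H) continue;
          // copy channel column x(., si, sj)
          std::memcpy(K.colptr(p) + C * (ki + kh * kj),
                      x.slice_colptr(sj, si), C * sizeof(double));
        }
      }
    }
  }
  return K;
}

static void col2im_acc(cube &dx, const mat &Kg, int kh, int kw, int stride,
                       int pad, int Hout, int Wout) {
  const int C = dx.n_rows, H = dx.n_cols, W = dx.n_slices;
  for (int j = 0; j < Wout; ++j) {
    for (int i = 0; i < Hout; ++i) {
      const int p = i + Hout * j;
      for (int kj = 0; kj < kw; ++kj) {
        const int sj = j * stride - pad + kj;
        if (sj < 0 || sj >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int si = i * stride - pad + ki;
          if (si < 0 || si >= H) continue;
          double *dst = dx.slice_colptr(sj, si);
          const double *src = Kg.colptr(p) + C * (ki + kh * kj);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube &x, const arma::mat &w,
                     const arma::vec &b, int kh, int kw, int stride, int pad) {
  const int H = x.n_cols, W = x.n_slices;
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  mat K = im2col(x, kh, kw, stride, pad, Hout, Wout);
  mat Y = w * K;                    // (Cout x Hout*Wout)
  Y.each_col() += b;
  cube out(Y.memptr(), w.n_rows, Hout, Wout);
  return out;
}

// separable Gaussian blur with reflective borders (for speckle smoothing);
// both passes run down columns (the second on the transpose) for locality
static mat blur_cols(const mat &x, const vec &k, int r) {
  const int H = x.n_rows, W = x.n_cols;
  mat out(H, W);
  const double *kp = k.memptr();
  for (int j = 0; j < W; ++j) {
    const double *c = x.colptr(j);
    double *o = out.colptr(j);
    for (int i = 0; i < r; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        s += kp[t + r] * c[ii];
      }
      o[i] = s;
    }
    for (int i = r; i < H - r; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) s += kp[t + r] * c[i + t];
      o[i] = s;
    }
    for (int i = std::max(r, H - r); i < H; ++i) {
      double s = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii >= H) ii = 2 * H - ii - 1;
        if (ii < 0) ii = -ii - 1;
        s += kp[t + r] * c[ii];
      }
      o[i] = s;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".gauss_blur")]]
arma::mat gauss_blur(const arma::mat &x, double sigma) {
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= accu(k);
  mat tmp = blur_cols(x, k, r);
  mat out = blur_cols(tmp.t(), k, r);
  return out.t();
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube &x, const arma::mat &w,
                     const arma::cube &dy, int kh, int kw, int stride,
                     int pad) {
  const int Hout = dy.n_cols, Wout = dy.n_slices, Cout = dy.n_rows;
  mat K = im2col(x, kh, kw, stride, pad, Hout, Wout);
  mat dYm(const_cast<double *>(dy.memptr()), Cout, Hout * Wout, false, true);
  mat dW = dYm * K.t();
  vec db = sum(dYm, 1);
  mat Kg = w.t() * dYm;             // (Cin*kh*kw x Hout*Wout)
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_acc(dx, Kg, kh, kw, stride, pad, Hout, Wout);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}
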