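// Convolution / pooling kernels for the spectrogram CNN.
// Layout conventions follow R column-major arrays:
//   feature maps  (H, W, C, N)
//   conv weights  (k, k, Cin, Cout)  -> flattened (k*k*Cin) x Cout matrix
// Convolutions are "same"-padded with odd kernel size; im2col + BLAS gemm.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d(x.attr("dim"));
  if (d.size() == 3) {
    H = d[0]; W = d[1]; C = d[2]; N = 1;
  } else if (d.size() == 4) {
    H = d[0]; W = d[1]; C = d[2]; N = d[3];
  } else {
    stop("expected a 3- or 4-dimensional array");
  }
}

// col(r, i + H*j) with r = ki + k*kj + k*k*c
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& col) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) col(r, i + H * j) = 0.0;
          } else {
            const double* src = xc + (size_t)jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + ki - pad;
              col(r, i + H * j) = (ii < 0 || ii >= H) ? 0.0 : src[ii];
            }
          }
        }
      }
    }
  }
}

// scatter-add inverse of im2col
static void col2im(const arma::mat& col, int H, int W, int C, int k, double* x) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          double* dst = xc + (size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - pad;
            if (ii >= 0 && ii < H) dst[ii] += col(r, i + H * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericVector w,
                               NumericVector b, bool relu) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd(w.attr("dim"));
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector y = alloc4d(H, W, Cout, N);
  arma::mat col(k * k * Cin, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, col);
    arma::mat ym = col.t() * wm; // (H*W) x Cout
    double* yp = y.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      double* dst = yp + (size_t)co * H * W;
      const double* src = ym.colptr(co);
      if (relu) {
        for (int t = 0; t < H * W; ++t) {
          const double v = src[t] + bias;
          dst[t] = v > 0.0 ? v : 0.0;
        }
      } else {
        for (int t = 0; t < H * W; ++t) dst[t] = src[t] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericVector w, NumericVector y,
                       NumericVector dy, bool relu) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd(w.attr("dim"));
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector dx = alloc4d(H, W, C, N);
  arma::mat dwm(k * k * Cin, Cout, arma::fill::zeros);
  arma::vec dbv(Cout, arma::fill::zeros);
  arma::mat col(k * k * Cin, H * W);
  arma::mat dz(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const double* yp = y.begin() + (size_t)n * H * W * Cout;
    const double* dyp = dy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* ysrc = yp + (size_t)co * H * W;
      const double* dsrc = dyp + (size_t)co * H * W;
      double* dst = dz.colptr(co);
      double acc = 0.0;
      if (relu) {
        for (int t = 0; t < H * W; ++t) {
          const double g = ysrc[t] > 0.0 ? dsrc[t] : 0.0;
          dst[t] = g;
          acc += g;
        }
      } else {
        for (int t = 0; t < H * W; ++t) {
          dst[t] = dsrc[t];
          acc += dsrc[t];
        }
      }
      dbv[co] += acc;
    }
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, col);
    dwm += col * dz;
    arma::mat dcol = wm * dz.t(); // (k*k*Cin) x (H*W)
    col2im(dcol, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  NumericVector dw(w.size());
  std::copy(dwm.begin(), dwm.end(), dw.begin());
  dw.attr("dim") = w.attr("dim");
  return List::create(Named("dx") = dx, Named("dw") = dw,
                      Named("db") = NumericVector(dbv.begin(), dbv.end()));
}

// Transposed (backward-data) convolution: maps a (H,W,Cout[,N]) tensor back
// through the kernel to (H,W,Cin[,N]). Used by relevance propagation.
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector s, NumericVector w) {
  int H, W, C, N;
  get_dims4(s, H, W, C, N);
  IntegerVector wdim(w.attr("dim"));
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (C != Cout) stop("channel mismatch between tensor and weights");
  const arma::mat wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector out = alloc4d(H, W, Cin, N);
  arma::mat sm(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const double* sp = s.begin() + (size_t)n * H * W * Cout;
    std::copy(sp, sp + (size_t)H * W * Cout, sm.begin());
    arma::mat dcol = wm * sm.t();
    col2im(dcol, H, W, Cin, k, out.begin() + (size_t)n * H * W * Cin);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small to pool");
  NumericVector y = alloc4d(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N); // 0-based within (H,W,C)
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    double* yp = y.begin() + (size_t)n * Ho * Wo * C;
    int* ip = idx.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)c * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int ii = 2 * i + di, jj = 2 * j + dj;
              const int lin = ii + H * jj;
              if (xc[lin] > best) {
                best = xc[lin];
                bidx = lin + c * H * W;
              }
            }
          }
          yp[i + Ho * j + c * Ho * Wo] = best;
          ip[i + Ho * j + c * Ho * Wo] = bidx;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector dy,
                                   IntegerVector in_dim) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dx = alloc4d(H, W, C, N);
  const size_t per_out = (size_t)Ho * Wo * C;
  const size_t per_in = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    const int* ip = idx.begin() + n * per_out;
    const double* dp = dy.begin() + n * per_out;
    double* xp = dx.begin() + n * per_in;
    for (size_t t = 0; t < per_out; ++t) xp[ip[t]] += dp[t];
  }
  return dx;
}
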