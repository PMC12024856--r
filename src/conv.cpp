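// Convolution kernels for the full-resolution network engine.
//
// Tensor layout everywhere: column-major R array with dim (C, H, W, N),
// i.e. channels fastest.  "Same" padding is implicit: pad = d*(k-1)/2,
// so spatial size is preserved for any odd kernel and dilation.
//
// Standard convs use per-sample im2col + BLAS GEMM (via Armadillo);
// k = 1 short-circuits to a single GEMM over the whole batch.
// Depthwise convs use direct loops (their FLOP count is negligible).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& C, int& H, int& W, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (C,H,W,N)");
  C = d[0]; H = d[1]; W = d[2]; N = d[3];
}

// Fill the im2col patch matrix P (C*k*k x H*W) for sample n.
// Row index = c + C*(u + k*v) for tap (u, v); column = i + H*j.
static void im2col(const double* x, double* P, int C, int H, int W,
                   int k, int d, int n) {
  const int p = d * (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t rows = (size_t)C * k * k;
  const double* xs = x + (size_t)n * C * HW;
  std::fill(P, P + rows * HW, 0.0);
  for (int v = 0; v < k; ++v) {
    for (int u = 0; u < k; ++u) {
      const size_t r0 = (size_t)C * (u + k * v);
      for (int j = 0; j < W; ++j) {
        const int js = j + v * d - p;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + u * d - p;
          if (is < 0 || is >= H) continue;
          std::memcpy(P + ((size_t)(i + (size_t)H * j)) * rows + r0,
                      xs + ((size_t)is + (size_t)H * js) * C,
                      C * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix back onto the input gradient.
static void col2im_add(double* gx, const double* gP, int C, int H, int W,
                       int k, int d, int n) {
  const int p = d * (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t rows = (size_t)C * k * k;
  double* gxs = gx + (size_t)n * C * HW;
  for (int v = 0; v < k; ++v) {
    for (int u = 0; u < k; ++u) {
      const size_t r0 = (size_t)C * (u + k * v);
      for (int j = 0; j < W; ++j) {
        const int js = j + v * d - p;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + u * d - p;
          if (is < 0 || is >= H) continue;
          const double* src = gP + ((size_t)(i + (size_t)H * j)) * rows + r0;
          double* dst = gxs + ((size_t)is + (size_t)H * js) * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// Reshape weights (Cout, Cin, k, k) into the GEMM matrix (Cout x Cin*k*k)
// whose column order matches im2col rows.
static arma::mat weight_mat(const NumericVector& w, int Cout, int Cin, int k) {
  arma::mat Wm(Cout, (size_t)Cin * k * k);
  const double* wp = w.begin();
  for (int v = 0; v < k; ++v)
    for (int u = 0; u < k; ++u)
      for (int c = 0; c < Cin; ++c) {
        const size_t col = c + (size_t)Cin * (u + k * v);
        for (int o = 0; o < Cout; ++o)
          Wm(o, col) = wp[o + (size_t)Cout * (c + (size_t)Cin * (u + (size_t)k * v))];
      }
  return Wm;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int dilation) {
  int C, H, W, N; dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  if (k % 2 == 0) stop("conv2d: kernel size must be odd");
  const size_t HW = (size_t)H * W;
  NumericVector out((size_t)Cout * HW * N);
  out.attr("dim") = IntegerVector::create(Cout, H, W, N);
  arma::mat Wm = weight_mat(w, Cout, Cin, k);
  arma::colvec bv(b.begin(), Cout, false);

  if (k == 1 && dilation == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, HW * N, false);
    arma::mat Y(out.begin(), Cout, HW * N, false);
    Y = Wm * X;
    Y.each_col() += bv;
    return out;
  }
  arma::mat P((size_t)C * k * k, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), P.memptr(), C, H, W, k, dilation, n);
    arma::mat Y(out.begin() + (size_t)n * Cout * HW, Cout, HW, false);
    Y = Wm * P;
    Y.each_col() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int dilation) {
  int C, H, W, N; dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[0], Cin = wd[1], k = wd[2];
  const size_t HW = (size_t)H * W;
  arma::mat Wm = weight_mat(w, Cout, Cin, k);

  NumericVector gx((size_t)C * HW * N);
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  arma::mat gWm(Cout, (size_t)Cin * k * k, arma::fill::zeros);
  arma::colvec gb(Cout, arma::fill::zeros);

  if (k == 1 && dilation == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, HW * N, false);
    arma::mat Gy(const_cast<double*>(gy.begin()), Cout, HW * N, false);
    arma::mat Gx(gx.begin(), C, HW * N, false);
    Gx = Wm.t() * Gy;
    gWm = Gy * X.t();
    gb = arma::sum(Gy, 1);
  } else {
    arma::mat P((size_t)C * k * k, HW);
    arma::mat gP((size_t)C * k * k, HW);
    for (int n = 0; n < N; ++n) {
      im2col(x.begin(), P.memptr(), C, H, W, k, dilation, n);
      arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * Cout * HW,
                   Cout, HW, false);
      gWm += Gy * P.t();
      gP = Wm.t() * Gy;
      col2im_add(gx.begin(), gP.memptr(), C, H, W, k, dilation, n);
      gb += arma::sum(Gy, 1);
    }
  }
  // back to (Cout, Cin, k, k) layout
  NumericVector gw((size_t)Cout * Cin * k * k);
  gw.attr("dim") = IntegerVector::create(Cout, Cin, k, k);
  for (int v = 0; v < k; ++v)
    for (int u = 0; u < k; ++u)
      for (int c = 0; c < Cin; ++c) {
        const size_t col = c + (size_t)Cin * (u + k * v);
        for (int o = 0; o < Cout; ++o)
          gw[o + (size_t)Cout * (c + (size_t)Cin * (u + (size_t)k * v))] = gWm(o, col);
      }
  NumericVector gbv(gb.begin(), gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}

// Depthwise convolutions stream tap-by-tap over the valid output rectangle
// (bounds hoisted out of the pixel loops; the channel loop is contiguous).

// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int dilation) {
  int C, H, W, N; dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  if (wd[0] != C) stop("dwconv2d: channel mismatch (%d vs %d)", C, wd[0]);
  const int k = wd[1];
  if (k % 2 == 0) stop("dwconv2d: kernel size must be odd");
  const int p = dilation * (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  NumericVector out((size_t)C * HW * N);
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* op = out.begin();
  for (size_t px = 0; px < HW * (size_t)N; ++px) {
    double* o = op + px * C;
    for (int c = 0; c < C; ++c) o[c] = b[c];
  }
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * C * HW;
    double* os = op + (size_t)n * C * HW;
    for (int v = 0; v < k; ++v) {
      const int dj = v * dilation - p;
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      for (int u = 0; u < k; ++u) {
        const int di = u * dilation - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const double* wt = wp + (size_t)C * (u + (size_t)k * v);
        for (int j = j0; j < j1; ++j) {
          const double* xi = xs + ((size_t)(i0 + di) + (size_t)H * (j + dj)) * C;
          double* o = os + ((size_t)i0 + (size_t)H * j) * C;
          const int rows = i1 - i0;
          for (int r = 0; r < rows; ++r) {
            const double* xr = xi + (size_t)r * C;
            double* orow = o + (size_t)r * C;
            for (int c = 0; c < C; ++c) orow[c] += wt[c] * xr[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int dilation) {
  int C, H, W, N; dims4(x, C, H, W, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[1];
  const int p = dilation * (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  NumericVector gx((size_t)C * HW * N);
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  NumericVector gw((size_t)C * k * k);
  gw.attr("dim") = IntegerVector::create(C, k, k);
  NumericVector gb(C);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* gp = gy.begin();
  for (size_t px = 0; px < HW * (size_t)N; ++px) {
    const double* g = gp + px * C;
    for (int c = 0; c < C; ++c) gb[c] += g[c];
  }
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * C * HW;
    const double* gs = gp + (size_t)n * C * HW;
    double* gxs = gx.begin() + (size_t)n * C * HW;
    for (int v = 0; v < k; ++v) {
      const int dj = v * dilation - p;
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      for (int u = 0; u < k; ++u) {
        const int di = u * dilation - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const double* wt = wp + (size_t)C * (u + (size_t)k * v);
        double* gwt = gw.begin() + (size_t)C * (u + (size_t)k * v);
        for (int j = j0; j < j1; ++j) {
          const size_t src = ((size_t)(i0 + di) + (size_t)H * (j + dj)) * C;
          const size_t dst = ((size_t)i0 + (size_t)H * j) * C;
          const int rows = i1 - i0;
          for (int r = 0; r < rows; ++r) {
            const double* xr = xs + src + (size_t)r * C;
            double* gxr = gxs + src + (size_t)r * C;
            const double* g = gs + dst + (size_t)r * C;
            for (int c = 0; c < C; ++c) {
              gwt[c] += g[c] * xr[c];
              gxr[c] += g[c] * wt[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
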