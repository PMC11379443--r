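// Low-level tensor kernels for the convolutional autoencoder.
//
// Layout conventions (R column-major):
//   activations: 4-d array (H, W, C, N)
//   conv weights: (k, k, C_in, C_out);  transposed-conv weights: (k, k, C_out, C_in)
// All convolutions use square kernels with symmetric zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather k x k x C patches of x into a (k*k*C, Ho*Wo) matrix.
// Row order: kernel-row fastest, then kernel-col, then channel (matches the
// column-major flattening of an R (k, k, C, ...) weight array).
// Column order: output row fastest (matches an R (Ho, Wo, ...) array).
static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* cptr = cols.colptr((size_t)wo * Ho + ho);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int w = wo * stride + j - pad;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = ho * stride + i - pad;
            if (h < 0 || h >= H) continue;
            cptr[(size_t)c * k * k + (size_t)j * k + i] = x(h, w, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch columns back into an (H, W, C) cube.
static void col2im(const arma::mat& cols, int k, int stride, int pad,
                   int Ho, int Wo, arma::cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* cptr = cols.colptr((size_t)wo * Ho + ho);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int w = wo * stride + j - pad;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = ho * stride + i - pad;
            if (h < 0 || h >= H) continue;
            gx(h, w, c) += cptr[(size_t)c * k * k + (size_t)j * k + i];
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input has %d channels, weights expect %d", C, Cin);
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("non-positive convolution output size");

  arma::mat wm(w.begin(), (size_t)k * k * Cin, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::cube xn(x.begin() + (size_t)n * H * W * C, H, W, C, false);
    arma::mat cols = im2col(xn, k, stride, pad, Ho, Wo);
    arma::mat yn = cols.t() * wm;          // (Ho*Wo, Cout)
    yn.each_row() += bv;
    std::copy(yn.begin(), yn.end(), y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool need_gx = true) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w"), gd = dims4(gy, "gy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat wm(w.begin(), (size_t)k * k * C, Cout, false);
  arma::mat gw((size_t)k * k * C, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  NumericVector gx = need_gx ? alloc4(H, W, C, N) : alloc4(1, 1, 1, 1);
  for (int n = 0; n < N; ++n) {
    arma::cube xn(x.begin() + (size_t)n * H * W * C, H, W, C, false);
    arma::mat gyn(gy.begin() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false);
    arma::mat cols = im2col(xn, k, stride, pad, Ho, Wo);
    gw += cols * gyn;
    gb += arma::sum(gyn, 0);
    if (need_gx) {
      arma::mat gcols = wm * gyn.t();      // (k*k*C, Ho*Wo)
      arma::cube gxn(gx.begin() + (size_t)n * H * W * C, H, W, C, false, true);
      col2im(gcols, k, stride, pad, Ho, Wo, gxn);
    }
  }
  NumericVector gw_out(gw.begin(), gw.end());
  gw_out.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw_out,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector cpp_tconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                              int stride, int pad) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  if (wd[3] != Cin) stop("input has %d channels, weights expect %d", Cin, wd[3]);
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;

  arma::mat wm(w.begin(), (size_t)k * k * Cout, Cin, false);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(x.begin() + (size_t)n * H * W * Cin, (size_t)H * W, Cin, false);
    arma::mat gcols = wm * xn.t();         // (k*k*Cout, H*W)
    arma::cube yn(y.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout,
                  false, true);
    col2im(gcols, k, stride, pad, H, W, yn);
    for (int c = 0; c < Cout; ++c) yn.slice(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad) {
  IntegerVector xd = dims4(x, "x"), wd = dims4(w, "w"), gd = dims4(gy, "gy");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat wm(w.begin(), (size_t)k * k * Cout, Cin, false);
  arma::mat gw((size_t)k * k * Cout, Cin, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx = alloc4(H, W, Cin, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(x.begin() + (size_t)n * H * W * Cin, (size_t)H * W, Cin, false);
    arma::cube gyn(gy.begin() + (size_t)n * Ho * Wo * Cout, Ho, Wo, Cout, false);
    arma::mat cols = im2col(gyn, k, stride, pad, H, W);   // (k*k*Cout, H*W)
    gw += cols * xn;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(gyn.slice(c));
    arma::mat gxn = cols.t() * wm;         // (H*W, Cin)
    std::copy(gxn.begin(), gxn.end(), gx.begin() + (size_t)n * H * W * Cin);
  }
  NumericVector gw_out(gw.begin(), gw.end());
  gw_out.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw_out,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Local mean over all fully-interior win x win windows (valid positions),
// computed per (channel, sample) slab via integral images.
// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector x, int win) {
  IntegerVector xd = dims4(x, "x");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H - win + 1, Wo = W - win + 1;
  if (Ho <= 0 || Wo <= 0) stop("window larger than image");
  const double inv = 1.0 / ((double)win * win);
  NumericVector y = alloc4(Ho, Wo, C, N);
  arma::mat I(H + 1, W + 1);
  for (int s = 0; s < C * N; ++s) {
    arma::mat xs(x.begin() + (size_t)s * H * W, H, W, false);
    I.zeros();
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        I(h + 1, w + 1) = xs(h, w) + I(h, w + 1) + I(h + 1, w) - I(h, w);
    double* yp = y.begin() + (size_t)s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[(size_t)wo * Ho + ho] =
          inv * (I(ho + win, wo + win) - I(ho, wo + win) -
                 I(ho + win, wo) + I(ho, wo));
  }
  return y;
}

// Adjoint of cpp_box_mean: out(h, w) = sum over windows covering (h, w) of
// g(window) / win^2. Computed as a clamped box sum over g via integral images.
// [[Rcpp::export]]
NumericVector cpp_box_adjoint(NumericVector g, int win, int H, int W) {
  IntegerVector gd = dims4(g, "g");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  const double inv = 1.0 / ((double)win * win);
  NumericVector y = alloc4(H, W, C, N);
  arma::mat I(Ho + 1, Wo + 1);
  for (int s = 0; s < C * N; ++s) {
    arma::mat gs(g.begin() + (size_t)s * Ho * Wo, Ho, Wo, false);
    I.zeros();
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        I(h + 1, w + 1) = gs(h, w) + I(h, w + 1) + I(h + 1, w) - I(h, w);
    double* yp = y.begin() + (size_t)s * H * W;
    for (int w = 0; w < W; ++w) {
      // windows with top-left (ho, wo), ho in [h-win+1, h], clamped to valid
      const int wlo = std::max(0, w - win + 1), whi = std::min(w, Wo - 1);
      for (int h = 0; h < H; ++h) {
        const int hlo = std::max(0, h - win + 1), hhi = std::min(h, Ho - 1);
        if (hlo > hhi || wlo > whi) { yp[(size_t)w * H + h] = 0.0; continue; }
        yp[(size_t)w * H + h] =
          inv * (I(hhi + 1, whi + 1) - I(hlo, whi + 1) -
                 I(hhi + 1, wlo) + I(hlo, wlo));
      }
    }
  }
  return y;
}

// In-place Adam update: p, m, v are mutated (the caller owns them
// exclusively; checkpoints must deep-copy before aliasing these buffers).
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector m, NumericVector v,
                     NumericVector g, double lr, double beta1, double beta2,
                     double bc1, double bc2, double eps) {
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam buffer length mismatch");
  double* pp = p.begin(); double* pm = m.begin();
  double* pv = v.begin(); const double* pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
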