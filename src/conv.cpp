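// Convolution / transposed-convolution primitives for the encoder-decoder.
// Single precision internally (BLAS sgemm); R interface is double.
// Geometry: 'same'-style zero padding, column-major HxWxC cubes matching R
// arrays. im2col column layout: kk = (c*k + di)*k + dj.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Valid output range [lo, hi] for one kernel offset d: 0 <= o*s - p + d < n.
static inline void valid_range(int n, int s, int p, int d, int nout,
                               int& lo, int& hi) {
  lo = (p - d + s - 1) / s;       // ceil((p - d) / s), nonneg s
  if (lo < 0) lo = 0;
  hi = (n - 1 - d + p) / s;
  if (hi > nout - 1) hi = nout - 1;
}

static fmat im2col(const fcube& x, int k, int s, int p, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat col((uword)Ho * Wo, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.slice_memptr(c);
    for (int di = 0; di < k; ++di) {
      int io_lo, io_hi;
      valid_range(H, s, p, di, Ho, io_lo, io_hi);
      if (io_hi < io_lo) continue;
      for (int dj = 0; dj < k; ++dj) {
        const uword kk = ((uword)c * k + di) * k + dj;
        float* dst = col.colptr(kk);
        int jo_lo, jo_hi;
        valid_range(W, s, p, dj, Wo, jo_lo, jo_hi);
        for (int jo = jo_lo; jo <= jo_hi; ++jo) {
          const int j = jo * s - p + dj;
          const float* src = xs + (uword)j * H + (io_lo * s - p + di);
          float* d2 = dst + (uword)jo * Ho + io_lo;
          const int len = io_hi - io_lo + 1;
          if (s == 1) {
            std::memcpy(d2, src, len * sizeof(float));
          } else {
            for (int t = 0; t < len; ++t) d2[t] = src[(uword)t * s];
          }
        }
      }
    }
  }
  return col;
}

static fcube col2im_add(const fmat& col, int H, int W, int C,
                        int k, int s, int p, int Ho, int Wo) {
  fcube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* xs = x.slice_memptr(c);
    for (int di = 0; di < k; ++di) {
      int io_lo, io_hi;
      valid_range(H, s, p, di, Ho, io_lo, io_hi);
      if (io_hi < io_lo) continue;
      for (int dj = 0; dj < k; ++dj) {
        const uword kk = ((uword)c * k + di) * k + dj;
        const float* src = col.colptr(kk);
        int jo_lo, jo_hi;
        valid_range(W, s, p, dj, Wo, jo_lo, jo_hi);
        for (int jo = jo_lo; jo <= jo_hi; ++jo) {
          const int j = jo * s - p + dj;
          float* d2 = xs + (uword)j * H + (io_lo * s - p + di);
          const float* s2 = src + (uword)jo * Ho + io_lo;
          const int len = io_hi - io_lo + 1;
          if (s == 1) {
            for (int t = 0; t < len; ++t) d2[t] += s2[t];
          } else {
            for (int t = 0; t < len; ++t) d2[(uword)t * s] += s2[t];
          }
        }
      }
    }
  }
  return x;
}

static fcube as_f(const cube& x) { return conv_to<fcube>::from(x); }

static Rcpp::NumericVector wrap_cube(const fcube& y) {
  Rcpp::NumericVector out(y.n_elem);
  std::copy(y.begin(), y.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
  return out;
}

// y = relu?(conv(x, W) + b); W is (k*k*Cin) x Cout
// [[Rcpp::export]]
Rcpp::NumericVector cb_conv_fwd(const arma::cube& x_, const arma::mat& W_,
                                const arma::vec& b_, int k, int stride,
                                int pad, bool relu) {
  const fcube x = as_f(x_);
  const fmat W = conv_to<fmat>::from(W_);
  const fvec b = conv_to<fvec>::from(b_);
  const int Ho = out_dim(x.n_rows, k, stride, pad);
  const int Wo = out_dim(x.n_cols, k, stride, pad);
  const int Cout = W.n_cols;
  fmat ym = im2col(x, k, stride, pad, Ho, Wo) * W;
  ym.each_row() += b.t();
  if (relu) ym.for_each([](float& v) { if (v < 0) v = 0; });
  fcube y(Ho, Wo, Cout);
  std::copy(ym.begin(), ym.end(), y.begin());
  return wrap_cube(y);
}

// gy is the gradient at the (post-ReLU) output y.
// [[Rcpp::export]]
Rcpp::List cb_conv_bwd(const arma::cube& x_, const arma::mat& W_,
                       const arma::cube& gy_, const arma::cube& y_,
                       int k, int stride, int pad, bool relu, bool need_gx) {
  const fcube x = as_f(x_);
  const fmat W = conv_to<fmat>::from(W_);
  fcube gy = as_f(gy_);
  if (relu) {
    const fcube y = as_f(y_);
    for (uword i = 0; i < gy.n_elem; ++i) if (y(i) <= 0) gy(i) = 0;
  }
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const fmat col = im2col(x, k, stride, pad, Ho, Wo);
  fmat gym((uword)Ho * Wo, Cout);
  std::copy(gy.begin(), gy.end(), gym.begin());
  const fmat gW = col.t() * gym;
  const frowvec gb = sum(gym, 0);
  Rcpp::List out;
  out["gW"] = Rcpp::wrap(conv_to<mat>::from(gW));
  out["gb"] = Rcpp::wrap(conv_to<vec>::from(gb.t()));
  if (need_gx) {
    const fmat gcol = gym * W.t();
    out["gx"] = wrap_cube(col2im_add(gcol, x.n_rows, x.n_cols, x.n_slices,
                                     k, stride, pad, Ho, Wo));
  }
  return out;
}

// Transposed convolution: W is (k*k*Cout) x Cin, i.e. the weight of the
// adjoint convolution mapping the (Ho,Wo,Cout) output back to the input grid.
// Requires (Ho + 2*pad - k)/stride + 1 == nrow(x).
// [[Rcpp::export]]
Rcpp::NumericVector cb_deconv_fwd(const arma::cube& x_, const arma::mat& W_,
                                  const arma::vec& b_, int k, int stride,
                                  int pad, int Ho, int Wo, bool relu) {
  const fcube x = as_f(x_);
  const fmat W = conv_to<fmat>::from(W_);
  const fvec b = conv_to<fvec>::from(b_);
  const int Cout = W.n_rows / (k * k);
  if (out_dim(Ho, k, stride, pad) != (int)x.n_rows ||
      out_dim(Wo, k, stride, pad) != (int)x.n_cols)
    Rcpp::stop("deconv output size inconsistent with input and geometry");
  fmat xm((uword)x.n_rows * x.n_cols, x.n_slices);
  std::copy(x.begin(), x.end(), xm.begin());
  const fmat colY = xm * W.t();
  fcube y = col2im_add(colY, Ho, Wo, Cout, k, stride, pad,
                       x.n_rows, x.n_cols);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  if (relu) y.for_each([](float& v) { if (v < 0) v = 0; });
  return wrap_cube(y);
}

// [[Rcpp::export]]
Rcpp::List cb_deconv_bwd(const arma::cube& x_, const arma::mat& W_,
                         const arma::cube& gy_, const arma::cube& y_,
                         int k, int stride, int pad, bool relu, bool need_gx) {
  const fcube x = as_f(x_);
  const fmat W = conv_to<fmat>::from(W_);
  fcube gy = as_f(gy_);
  if (relu) {
    const fcube y = as_f(y_);
    for (uword i = 0; i < gy.n_elem; ++i) if (y(i) <= 0) gy(i) = 0;
  }
  const int Hi = x.n_rows, Wi = x.n_cols;
  const fmat gcolY = im2col(gy, k, stride, pad, Hi, Wi);
  fmat xm((uword)Hi * Wi, x.n_slices);
  std::copy(x.begin(), x.end(), xm.begin());
  const fmat gW = gcolY.t() * xm;
  fvec gb(gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c) gb(c) = accu(gy.slice(c));
  Rcpp::List out;
  out["gW"] = Rcpp::wrap(conv_to<mat>::from(gW));
  out["gb"] = Rcpp::wrap(conv_to<vec>::from(gb));
  if (need_gx) {
    const fmat gxm = gcolY * W;
    fcube gx(Hi, Wi, x.n_slices);
    std::copy(gxm.begin(), gxm.end(), gx.begin());
    out["gx"] = wrap_cube(gx);
  }
  return out;
}
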