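// Fused layer kernels: (de)convolution -> optional instance norm -> optional
// ReLU, with a C++-side cache (im2col matrix, normalized activations,
// post-activation output, all single precision) handed back to R as an
// external pointer so the backward pass neither re-im2cols nor re-converts.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const float IN_EPS_F = 1e-5f;

// shared with conv.cpp (duplicated here to keep translation units simple)
static inline int out_dim_l(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static inline void valid_range_l(int n, int s, int p, int d, int nout,
                                 int& lo, int& hi) {
  lo = (p - d + s - 1) / s;
  if (lo < 0) lo = 0;
  hi = (n - 1 - d + p) / s;
  if (hi > nout - 1) hi = nout - 1;
}

// The column matrix is allocated unzeroed; only the padding entries (the
// thin invalid strips at the field border) are zeroed explicitly, which
// avoids a full-size memset per call.
static fmat im2col_l(const fcube& x, int k, int s, int p, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat col((uword)Ho * Wo, (uword)k * k * C, fill::none);
  for (int c = 0; c < C; ++c) {
    const float* xs = x.slice_memptr(c);
    for (int di = 0; di < k; ++di) {
      int io_lo, io_hi;
      valid_range_l(H, s, p, di, Ho, io_lo, io_hi);
      for (int dj = 0; dj < k; ++dj) {
        const uword kk = ((uword)c * k + di) * k + dj;
        float* dst = col.colptr(kk);
        int jo_lo, jo_hi;
        valid_range_l(W, s, p, dj, Wo, jo_lo, jo_hi);
        if (io_hi < io_lo || jo_hi < jo_lo) {
          std::memset(dst, 0, (uword)Ho * Wo * sizeof(float));
          continue;
        }
        if (jo_lo > 0) {
          std::memset(dst, 0, (uword)jo_lo * Ho * sizeof(float));
        }
        if (jo_hi < Wo - 1) {
          std::memset(dst + (uword)(jo_hi + 1) * Ho, 0,
                      (uword)(Wo - 1 - jo_hi) * Ho * sizeof(float));
        }
        for (int jo = jo_lo; jo <= jo_hi; ++jo) {
          const int j = jo * s - p + dj;
          const float* src = xs + (uword)j * H + (io_lo * s - p + di);
          float* d2 = dst + (uword)jo * Ho + io_lo;
          const int len = io_hi - io_lo + 1;
          if (io_lo > 0) {
            std::memset(dst + (uword)jo * Ho, 0, io_lo * sizeof(float));
          }
          if (io_hi < Ho - 1) {
            std::memset(dst + (uword)jo * Ho + io_hi + 1, 0,
                        (Ho - 1 - io_hi) * sizeof(float));
          }
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

static void col2im_add_l(const fmat& col, fcube& x, int k, int s, int p,
                         int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    float* xs = x.slice_memptr(c);
    for (int di = 0; di < k; ++di) {
      int io_lo, io_hi;
      valid_range_l(H, s, p, di, Ho, io_lo, io_hi);
      if (io_hi < io_lo) continue;
      for (int dj = 0; dj < k; ++dj) {
        const uword kk = ((uword)c * k + di) * k + dj;
        const float* src = col.colptr(kk);
        int jo_lo, jo_hi;
        valid_range_l(W, s, p, dj, Wo, jo_lo, jo_hi);
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
}

struct LayerCache {
  fmat col;   // conv: im2col(x); deconv: flattened input xm
  fmat zh;    // instance-normalized pre-activation (N x C), if norm
  fvec sd;    // per-channel sd, if norm
  fmat yf;    // post-activation output (N x C), kept when relu
  int Hx, Wx, Cx;   // input geometry (for gx)
  int Ho, Wo;       // output geometry
};

typedef Rcpp::XPtr<LayerCache> CachePtr;

static Rcpp::NumericVector wrap_mat_as_cube(const fmat& m, int H, int W,
                                            int C) {
  Rcpp::NumericVector out(m.n_elem);
  std::copy(m.begin(), m.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  return out;
}

// In-place instance norm + optional ReLU on z (N x C); fills zh, sd.
static void in_relu(fmat& z, const fvec& gamma, const fvec& beta,
                    bool relu, bool norm, fmat& zh, fvec& sd,
                    bool want_cache) {
  const uword N = z.n_rows, C = z.n_cols;
  if (norm) {
    if (want_cache) { zh.set_size(N, C); sd.set_size(C); }
    for (uword c = 0; c < C; ++c) {
      float* zc = z.colptr(c);
      double s = 0, ss = 0;
      for (uword i = 0; i < N; ++i) { s += zc[i]; ss += (double)zc[i] * zc[i]; }
      const float mu = (float)(s / N);
      const float sdc = std::sqrt((float)(ss / N) - mu * mu + IN_EPS_F);
      const float a = gamma(c) / sdc;
      const float b = beta(c) - mu * a;
      if (want_cache) {
        sd(c) = sdc;
        float* zhc = zh.colptr(c);
        const float inv = 1.0f / sdc;
        for (uword i = 0; i < N; ++i) {
          zhc[i] = (zc[i] - mu) * inv;
          zc[i] = gamma(c) * zhc[i] + beta(c);
        }
      } else {
        for (uword i = 0; i < N; ++i) zc[i] = a * zc[i] + b;
      }
    }
  }
  if (relu) z.for_each([](float& v) { if (v < 0) v = 0; });
}

// [[Rcpp::export]]
Rcpp::List cb_layer_fwd(const arma::cube& x_, const arma::mat& W_,
                        const arma::vec& b_, int k, int stride, int pad,
                        bool relu, const arma::vec& gamma_,
                        const arma::vec& beta_, bool want_cache) {
  const fcube x = conv_to<fcube>::from(x_);
  const fmat W = conv_to<fmat>::from(W_);
  const fvec b = conv_to<fvec>::from(b_);
  const bool norm = gamma_.n_elem > 0;
  const fvec gamma = conv_to<fvec>::from(gamma_);
  const fvec beta = conv_to<fvec>::from(beta_);
  const int Ho = out_dim_l(x.n_rows, k, stride, pad);
  const int Wo = out_dim_l(x.n_cols, k, stride, pad);
  LayerCache* cache = new LayerCache();
  cache->Hx = x.n_rows; cache->Wx = x.n_cols; cache->Cx = x.n_slices;
  cache->Ho = Ho; cache->Wo = Wo;
  fmat col = im2col_l(x, k, stride, pad, Ho, Wo);
  fmat y = col * W;
  y.each_row() += b.t();
  if (want_cache) cache->col = std::move(col);
  in_relu(y, gamma, beta, relu, norm, cache->zh, cache->sd, want_cache);
  Rcpp::NumericVector yout = wrap_mat_as_cube(y, Ho, Wo, W.n_cols);
  if (want_cache && relu) cache->yf = std::move(y);
  CachePtr ptr(cache, true);
  return Rcpp::List::create(Rcpp::Named("y") = yout,
                            Rcpp::Named("cache") = ptr);
}

// Shared IN/ReLU backward: converts gy (R cube) to an N x C fmat with the
// ReLU mask and instance-norm backprop applied; fills ggamma/gbeta.
static fmat pre_bwd(const arma::cube& gy_, const LayerCache* cache,
                    const fvec& gamma, bool relu, bool norm,
                    fvec& ggamma, fvec& gbeta) {
  const uword N = (uword)gy_.n_rows * gy_.n_cols;
  const uword C = gy_.n_slices;
  fmat g(N, C);
  // double -> float copy; element order matches the N x C layout
  std::copy(gy_.begin(), gy_.end(), g.begin());
  if (relu) {
    for (uword i = 0; i < g.n_elem; ++i) if (cache->yf(i) <= 0) g(i) = 0;
  }
  if (norm) {
    ggamma.set_size(C); gbeta.set_size(C);
    for (uword c = 0; c < C; ++c) {
      float* gc = g.colptr(c);
      const float* zc = cache->zh.colptr(c);
      double sg = 0, sgz = 0;
      for (uword i = 0; i < N; ++i) { sg += gc[i]; sgz += (double)gc[i] * zc[i]; }
      gbeta(c) = (float)sg;
      ggamma(c) = (float)sgz;
      const float m1 = gamma(c) * (float)(sg / N);
      const float m2 = gamma(c) * (float)(sgz / N);
      const float inv = 1.0f / cache->sd(c);
      for (uword i = 0; i < N; ++i) {
        gc[i] = (gamma(c) * gc[i] - m1 - zc[i] * m2) * inv;
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List cb_layer_bwd(SEXP cache_, const arma::mat& W_,
                        const arma::vec& gamma_, const arma::cube& gy_,
                        int k, int stride, int pad, bool relu,
                        bool need_gx) {
  CachePtr ptr(cache_);
  const LayerCache* cache = ptr.get();
  const fmat W = conv_to<fmat>::from(W_);
  const bool norm = gamma_.n_elem > 0;
  const fvec gamma = conv_to<fvec>::from(gamma_);
  fvec ggamma, gbeta_in;
  fmat g = pre_bwd(gy_, cache, gamma, relu, norm, ggamma, gbeta_in);
  const fmat gW = cache->col.t() * g;
  const frowvec gb = sum(g, 0);
  Rcpp::List out;
  out["gW"] = Rcpp::wrap(conv_to<mat>::from(gW));
  out["gb"] = Rcpp::wrap(conv_to<vec>::from(gb.t()));
  if (norm) {
    out["gamma"] = Rcpp::wrap(conv_to<vec>::from(ggamma));
    out["beta"] = Rcpp::wrap(conv_to<vec>::from(gbeta_in));
  }
  if (need_gx) {
    const fmat gcol = g * W.t();
    fcube gx(cache->Hx, cache->Wx, cache->Cx, fill::zeros);
    col2im_add_l(gcol, gx, k, stride, pad, cache->Ho, cache->Wo);
    Rcpp::NumericVector gxo(gx.n_elem);
    std::copy(gx.begin(), gx.end(), gxo.begin());
    gxo.attr("dim") = Rcpp::IntegerVector::create(cache->Hx, cache->Wx,
                                                  cache->Cx);
    out["gx"] = gxo;
  }
  return out;
}

// Transposed-convolution layer: W is (k*k*Cout) x Cin.
// [[Rcpp::export]]
Rcpp::List cb_delayer_fwd(const arma::cube& x_, const arma::mat& W_,
                          const arma::vec& b_, int k, int stride, int pad,
                          int Ho, int Wo, bool relu,
                          const arma::vec& gamma_, const arma::vec& beta_,
                          bool want_cache) {
  const fcube x = conv_to<fcube>::from(x_);
  const fmat W = conv_to<fmat>::from(W_);
  const fvec b = conv_to<fvec>::from(b_);
  const bool norm = gamma_.n_elem > 0;
  const fvec gamma = conv_to<fvec>::from(gamma_);
  const fvec beta = conv_to<fvec>::from(beta_);
  const int Cout = W.n_rows / (k * k);
  if (out_dim_l(Ho, k, stride, pad) != (int)x.n_rows ||
      out_dim_l(Wo, k, stride, pad) != (int)x.n_cols)
    Rcpp::stop("deconv output size inconsistent with input and geometry");
  LayerCache* cache = new LayerCache();
  cache->Hx = x.n_rows; cache->Wx = x.n_cols; cache->Cx = x.n_slices;
  cache->Ho = Ho; cache->Wo = Wo;
  fmat xm((uword)x.n_rows * x.n_cols, x.n_slices);
  std::copy(x.begin(), x.end(), xm.begin());
  const fmat colY = xm * W.t();
  fcube yc(Ho, Wo, Cout, fill::zeros);
  col2im_add_l(colY, yc, k, stride, pad, x.n_rows, x.n_cols);
  fmat y((uword)Ho * Wo, Cout);
  std::copy(yc.begin(), yc.end(), y.begin());
  y.each_row() += b.t();
  if (want_cache) cache->col = std::move(xm);
  in_relu(y, gamma, beta, relu, norm, cache->zh, cache->sd, want_cache);
  Rcpp::NumericVector yout = wrap_mat_as_cube(y, Ho, Wo, Cout);
  if (want_cache && relu) cache->yf = std::move(y);
  CachePtr ptr(cache, true);
  return Rcpp::List::create(Rcpp::Named("y") = yout,
                            Rcpp::Named("cache") = ptr);
}

// [[Rcpp::export]]
Rcpp::List cb_delayer_bwd(SEXP cache_, const arma::mat& W_,
                          const arma::vec& gamma_, const arma::cube& gy_,
                          int k, int stride, int pad, bool relu,
                          bool need_gx) {
  CachePtr ptr(cache_);
  const LayerCache* cache = ptr.get();
  const fmat W = conv_to<fmat>::from(W_);
  const bool norm = gamma_.n_elem > 0;
  const fvec gamma = conv_to<fvec>::from(gamma_);
  fvec ggamma, gbeta_in;
  fmat g = pre_bwd(gy_, cache, gamma, relu, norm, ggamma, gbeta_in);
  // g is the gradient at the (Ho x Wo x Cout) output, flattened N x C
  fcube gc(cache->Ho, cache->Wo, g.n_cols);
  std::copy(g.begin(), g.end(), gc.begin());
  const fmat gcolY = im2col_l(gc, k, stride, pad, cache->Hx, cache->Wx);
  const fmat gW = gcolY.t() * cache->col;
  const frowvec gb = sum(g, 0);
  Rcpp::List out;
  out["gW"] = Rcpp::wrap(conv_to<mat>::from(gW));
  out["gb"] = Rcpp::wrap(conv_to<vec>::from(gb.t()));
  if (norm) {
    out["gamma"] = Rcpp::wrap(conv_to<vec>::from(ggamma));
    out["beta"] = Rcpp::wrap(conv_to<vec>::from(gbeta_in));
  }
  if (need_gx) {
    const fmat gxm = gcolY * W;
    Rcpp::NumericVector gxo(gxm.n_elem);
    std::copy(gxm.begin(), gxm.end(), gxo.begin());
    gxo.attr("dim") = Rcpp::IntegerVector::create(cache->Hx, cache->Wx,
                                                  cache->Cx);
    out["gx"] = gxo;
  }
  return out;
}
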