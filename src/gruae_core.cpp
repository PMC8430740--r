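// Batched forward/backward passes for the three-layer GRU autoencoder and
// the feedforward autoencoder baseline. The GRU-AE path runs in single
// precision (training is minibatch-gradient based and tolerant of float
// rounding; master weights are kept in double on the R side); the small
// feedforward model runs in double so its gradients can be checked directly
// against central finite differences. Gate nonlinearities are computed in
// fused loops over raw memory: with -ffast-math gcc vectorizes expf/tanhf,
// which is where most of the time goes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct GruLayerF {
  fmat Wall, WallT;  // 3h x in and its transpose; rows stacked [u; r; c]
  fmat Uall, UallT;  // 3h x h
  uword h;
};

GruLayerF layer_from_list(const List& lp) {
  GruLayerF L;
  fmat Wu = conv_to<fmat>::from(Rcpp::as<mat>(lp["Wu"]));
  fmat Wr = conv_to<fmat>::from(Rcpp::as<mat>(lp["Wr"]));
  fmat Wc = conv_to<fmat>::from(Rcpp::as<mat>(lp["Wc"]));
  fmat Uu = conv_to<fmat>::from(Rcpp::as<mat>(lp["Uu"]));
  fmat Ur = conv_to<fmat>::from(Rcpp::as<mat>(lp["Ur"]));
  fmat Uc = conv_to<fmat>::from(Rcpp::as<mat>(lp["Uc"]));
  L.h = Wu.n_rows;
  L.Wall = join_cols(Wu, Wr, Wc);
  L.Uall = join_cols(Uu, Ur, Uc);
  L.WallT = L.Wall.t();
  L.UallT = L.Uall.t();
  return L;
}

// Per-layer activation caches for backpropagation through time.
// u, r, c, huc: N x h x T; h: N x h x (T+1) with slice 0 = h0.
struct LayerCache {
  fcube u, r, c, huc, h;
};

// u_t = sigma(a_u), r_t = sigma(a_r), c_t = tanh(a_c + r % huc),
// h_t = u % h_prev + (1-u) % c, from pre-activation blocks A (input path)
// and B (recurrent path), both N x 3h.
inline void gru_gates(uword n, const float* A, const float* B,
                      const float* hprev, float* u, float* r, float* c,
                      float* huc, float* hout) {
  #pragma omp simd
  for (uword i = 0; i < n; ++i)
    u[i] = 1.0f / (1.0f + expf(-(A[i] + B[i])));
  #pragma omp simd
  for (uword i = 0; i < n; ++i)
    r[i] = 1.0f / (1.0f + expf(-(A[n + i] + B[n + i])));
  #pragma omp simd
  for (uword i = 0; i < n; ++i) {
    huc[i] = B[2 * n + i];
    c[i] = tanhf(A[2 * n + i] + r[i] * huc[i]);
  }
  for (uword i = 0; i < n; ++i)
    hout[i] = u[i] * hprev[i] + (1.0f - u[i]) * c[i];
}

// Forward one GRU layer over all timesteps for a batch of sequences.
// X: N x in x T. Fills H (N x h x T). Caches only if cache != nullptr.
void layer_forward(const fcube& X, const GruLayerF& L, const fmat& h0,
                   fcube& H, LayerCache* cache) {
  const uword N = X.n_rows, T = X.n_slices, h = L.h, n = N * h;
  fmat hprev = h0;
  fmat u_, r_, c_, huc_;
  if (cache) {
    cache->u.set_size(N, h, T); cache->r.set_size(N, h, T);
    cache->c.set_size(N, h, T); cache->huc.set_size(N, h, T);
    cache->h.set_size(N, h, T + 1);
    cache->h.slice(0) = h0;
  } else {
    u_.set_size(N, h); r_.set_size(N, h); c_.set_size(N, h);
    huc_.set_size(N, h);
  }
  for (uword t = 0; t < T; ++t) {
    fmat A = X.slice(t) * L.WallT;  // N x 3h
    fmat B = hprev * L.UallT;       // N x 3h
    float* u = cache ? cache->u.slice_memptr(t) : u_.memptr();
    float* r = cache ? cache->r.slice_memptr(t) : r_.memptr();
    float* c = cache ? cache->c.slice_memptr(t) : c_.memptr();
    float* huc = cache ? cache->huc.slice_memptr(t) : huc_.memptr();
    gru_gates(n, A.memptr(), B.memptr(), hprev.memptr(),
              u, r, c, huc, H.slice_memptr(t));
    hprev = H.slice(t);
    if (cache) cache->h.slice(t + 1) = hprev;
  }
}

// BPTT for one layer. dH: N x h x T gradient w.r.t. emitted states.
// Fills dX (gradient w.r.t. layer inputs) unless null; accumulates weight
// gradients into gW (3h x in) and gU (3h x h).
void layer_backward(const fcube& X, const GruLayerF& L, const LayerCache& cc,
                    const fcube& dH, fmat& gW, fmat& gU, fcube* dX) {
  const uword N = X.n_rows, in = X.n_cols, T = X.n_slices, h = L.h, n = N * h;
  gW.zeros(3 * h, in);
  gU.zeros(3 * h, h);
  fmat dA(N, 3 * h), dB(N, 3 * h);
  fmat dh_carry(N, h, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const float* dHt = dH.slice_memptr(t);
    const float* u = cc.u.slice_memptr(t);
    const float* r = cc.r.slice_memptr(t);
    const float* c = cc.c.slice_memptr(t);
    const float* huc = cc.huc.slice_memptr(t);
    const float* hp = cc.h.slice_memptr(t);
    float* pdA = dA.memptr();
    float* pdB = dB.memptr();
    float* dhc = dh_carry.memptr();
    #pragma omp simd
    for (uword i = 0; i < n; ++i) {
      float dh = dHt[i] + dhc[i];
      float da_u = dh * (hp[i] - c[i]) * u[i] * (1.0f - u[i]);
      float da_c = dh * (1.0f - u[i]) * (1.0f - c[i] * c[i]);
      float da_r = da_c * huc[i] * r[i] * (1.0f - r[i]);
      pdA[i] = da_u;
      pdA[n + i] = da_r;
      pdA[2 * n + i] = da_c;
      pdB[i] = da_u;
      pdB[n + i] = da_r;
      pdB[2 * n + i] = da_c * r[i];
      dhc[i] = dh * u[i];  // remaining carry terms added via gemm below
    }
    gW += dA.t() * X.slice(t);
    gU += dB.t() * cc.h.slice(t);
    dh_carry += dB * L.Uall;
    if (dX) dX->slice(t) = dA * L.Wall;
  }
}

List grads_to_list(const fmat& gW, const fmat& gU, uword h) {
  return List::create(
      Named("Wu") = conv_to<mat>::from(gW.rows(0, h - 1)),
      Named("Uu") = conv_to<mat>::from(gU.rows(0, h - 1)),
      Named("Wr") = conv_to<mat>::from(gW.rows(h, 2 * h - 1)),
      Named("Ur") = conv_to<mat>::from(gU.rows(h, 2 * h - 1)),
      Named("Wc") = conv_to<mat>::from(gW.rows(2 * h, 3 * h - 1)),
      Named("Uc") = conv_to<mat>::from(gU.rows(2 * h, 3 * h - 1)));
}

}  // namespace

// Batched GRU-AE pass. X: N x C x T cube of normalized windows. params:
// list(layers = list(l1, l2, l3), Wy, by). h0: list of three N x h_k
// initial-state matrices or NULL (zeros). Returns the total loss (sum of
// half-squared errors over windows, timesteps and channels), per-timestep
// losses (N x T), final layer states, and optionally the reconstruction Y
// and the parameter gradients of the total loss.
// [[Rcpp::export]]
List cpp_gru_ae_run(const arma::cube& X_, const List& params,
                    SEXP h0_, bool want_grads, bool want_output) {
  fcube X = conv_to<fcube>::from(X_);
  const uword N = X.n_rows, C = X.n_cols, T = X.n_slices;

  List layers = params["layers"];
  GruLayerF L1 = layer_from_list(layers[0]);
  GruLayerF L2 = layer_from_list(layers[1]);
  GruLayerF L3 = layer_from_list(layers[2]);
  fmat Wy = conv_to<fmat>::from(Rcpp::as<mat>(params["Wy"]));  // C x h3
  fmat WyT = Wy.t();
  frowvec by = conv_to<frowvec>::from(
      Rcpp::as<rowvec>(Rcpp::wrap(params["by"])));

  fmat h01(N, L1.h, fill::zeros), h02(N, L2.h, fill::zeros),
       h03(N, L3.h, fill::zeros);
  if (h0_ != R_NilValue) {
    List h0(h0_);
    h01 = conv_to<fmat>::from(Rcpp::as<mat>(h0[0]));
    h02 = conv_to<fmat>::from(Rcpp::as<mat>(h0[1]));
    h03 = conv_to<fmat>::from(Rcpp::as<mat>(h0[2]));
  }

  LayerCache c1, c2, c3;
  fcube H1(N, L1.h, T), H2(N, L2.h, T), H3(N, L3.h, T);
  layer_forward(X, L1, h01, H1, want_grads ? &c1 : nullptr);
  layer_forward(H1, L2, h02, H2, want_grads ? &c2 : nullptr);
  layer_forward(H2, L3, h03, H3, want_grads ? &c3 : nullptr);

  // Fully connected sigmoid head and per-timestep half-squared-error loss.
  mat loss_t(N, T);
  fcube Y, dH3;
  if (want_output) Y.set_size(N, C, T);
  if (want_grads) dH3.set_size(N, L3.h, T);
  fmat gWy(C, L3.h, fill::zeros);
  frowvec gby(C, fill::zeros);
  fmat y(N, C), da_y(N, C);
  for (uword t = 0; t < T; ++t) {
    y = H3.slice(t) * WyT;
    y.each_row() += by;
    const float* xt = X.slice_memptr(t);
    float* py = y.memptr();
    double* plt = loss_t.colptr(t);
    for (uword i = 0; i < N; ++i) plt[i] = 0.0;
    #pragma omp simd
    for (uword i = 0; i < N * C; ++i) py[i] = 1.0f / (1.0f + expf(-py[i]));
    for (uword j = 0; j < C; ++j) {
      for (uword i = 0; i < N; ++i) {
        float e = py[j * N + i] - xt[j * N + i];
        plt[i] += 0.5 * double(e) * double(e);
      }
    }
    if (want_output) Y.slice(t) = y;
    if (want_grads) {
      float* pd = da_y.memptr();
      #pragma omp simd
      for (uword i = 0; i < N * C; ++i) {
        float yv = py[i];
        pd[i] = (yv - xt[i]) * yv * (1.0f - yv);
      }
      gWy += da_y.t() * H3.slice(t);
      gby += sum(da_y, 0);
      dH3.slice(t) = da_y * Wy;
    }
  }

  List out = List::create(
      Named("loss") = accu(loss_t),
      Named("loss_t") = loss_t,
      Named("states") = List::create(conv_to<mat>::from(H1.slice(T - 1)),
                                     conv_to<mat>::from(H2.slice(T - 1)),
                                     conv_to<mat>::from(H3.slice(T - 1))));
  if (want_output) out["Y"] = conv_to<cube>::from(Y);
  if (want_grads) {
    fmat gW3, gU3, gW2, gU2, gW1, gU1;
    fcube dH2(N, L2.h, T), dH1(N, L1.h, T);
    layer_backward(H2, L3, c3, dH3, gW3, gU3, &dH2);
    layer_backward(H1, L2, c2, dH2, gW2, gU2, &dH1);
    layer_backward(X, L1, c1, dH1, gW1, gU1, nullptr);
    out["grads"] = List::create(
        Named("layers") = List::create(grads_to_list(gW1, gU1, L1.h),
                                       grads_to_list(gW2, gU2, L2.h),
                                       grads_to_list(gW3, gU3, L3.h)),
        Named("Wy") = conv_to<mat>::from(gWy),
        Named("by") = conv_to<rowvec>::from(gby));
  }
  return out;
}

// Feedforward autoencoder (input -> 128 -> 32 -> 128 -> input by default),
// all sigmoid activations, per-sample half-squared-error loss. Double
// precision so gradients admit direct finite-difference checks. X: N x C.
// params: list(W1, b1, ..., W4, b4), Wk rows = output units of layer k.
// [[Rcpp::export]]
List cpp_ae_run(const arma::mat& X, const List& params, bool want_grads,
                bool want_output) {
  const uword N = X.n_rows;
  mat W[4];
  rowvec b[4];
  const char* wn[4] = {"W1", "W2", "W3", "W4"};
  const char* bn[4] = {"b1", "b2", "b3", "b4"};
  for (int k = 0; k < 4; ++k) {
    W[k] = Rcpp::as<mat>(params[wn[k]]);
    b[k] = Rcpp::as<rowvec>(Rcpp::wrap(params[bn[k]]));
  }
  mat Z[5];
  Z[0] = X;
  for (int k = 0; k < 4; ++k) {
    Z[k + 1] = 1.0 / (1.0 + exp(-(Z[k] * W[k].t() + repmat(b[k], N, 1))));
  }
  mat e = Z[4] - X;
  vec loss_i = 0.5 * sum(e % e, 1);

  List out = List::create(Named("loss") = accu(loss_i),
                          Named("loss_i") = loss_i);
  if (want_output) out["Y"] = Z[4];
  if (want_grads) {
    List g(8);
    mat d = e;
    for (int k = 3; k >= 0; --k) {
      mat da = d % Z[k + 1] % (1.0 - Z[k + 1]);
      g[2 * k] = mat(da.t() * Z[k]);
      g[2 * k + 1] = rowvec(sum(da, 0));
      if (k > 0) d = da * W[k];
    }
    g.attr("names") = Rcpp::CharacterVector::create("W1", "b1", "W2", "b2",
                                                    "W3", "b3", "W4", "b4");
    out["grads"] = g;
  }
  return out;
}
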