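// Training and inference backend for the stacked-LSTM regressor.
//
// Layout conventions shared with the R side:
//  * one layer's weights are packed as a 4H x (H + D) matrix with row blocks
//    [f; i; g; o] (g is the tanh candidate) and columns [h_{t-1} | x_t];
//  * sequences are batched column-wise: within a minibatch of B sequences of
//    length L, working matrices are (rows x B*L) with column t*B + b holding
//    time step t of sequence b;
//  * dropout (inverted, train only) acts on the hidden sequences between
//    stacked layers, never inside the recurrence or after the top layer.
//
// All randomness (epoch shuffling, dropout masks) comes from one mt19937_64
// seeded by the caller, so a training run is reproducible bit for bit.
// Workspaces are allocated once per training run and reused across steps,
// minibatches and epochs; the per-time-step cell updates run as raw loops
// over the gate blocks to avoid temporaries in the innermost path.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

// computation runs in single precision (the customary arithmetic for neural
// network training); the R interface stays double
using wmat = arma::fmat;
using wvec = arma::fvec;
using wcube = arma::fcube;
typedef float real_t;

static inline real_t sigmoid1(real_t z) {
  return 1.0f / (1.0f + std::exp(-z));
}

// Per-layer workspace for one minibatch (capacity B * L columns).
struct LayerWork {
  wmat G;      // 4H x BL activated gates (f, i, g, o row blocks)
  wmat C;      // H x BL cell states
  wmat TC;     // H x BL tanh(C)
  wmat Hprev;  // H x BL hidden state entering each step
  wmat Hout;   // H x BL hidden outputs (post-dropout = input to next layer)
  wmat mask;   // H x BL dropout mask (scaled), only when dropout is active
  wmat h;      // H x B carry
  wmat c;      // H x B carry
  wmat Gt;     // 4H x B step buffer
  wmat dh;     // H x B backward carries
  wmat dc;     // H x B
  wmat DG;     // 4H x BL pre-activation gate gradients
  void init(uword H, uword BL, uword B, bool dropout) {
    G.set_size(4 * H, BL); C.set_size(H, BL); TC.set_size(H, BL);
    Hprev.set_size(H, BL); Hout.set_size(H, BL);
    if (dropout) mask.set_size(H, BL);
    h.set_size(H, B); c.set_size(H, B); Gt.set_size(4 * H, B);
    dh.set_size(H, B); dc.set_size(H, B); DG.set_size(4 * H, BL);
  }
};

// Forward one layer over a minibatch block of B sequences x L steps.
// X is Din x B*L; results land in the workspace. When `train` is false only
// Hout is maintained.
static void layer_forward(const wmat& W, const wvec& b, const wmat& X,
                          uword B, uword L, bool train, LayerWork& w) {
  const uword H = W.n_rows / 4;
  const uword Din = W.n_cols - H;
  const wmat Wh = W.cols(0, H - 1);
  const wmat Wx = W.cols(H, H + Din - 1);
  const uword BL = B * L;

  // input projection for the whole block in one GEMM, biases added once
  w.G.cols(0, BL - 1) = Wx * X;
  w.G.cols(0, BL - 1).each_col() += b;

  w.h.zeros(); w.c.zeros();
  for (uword t = 0; t < L; ++t) {
    const uword c0 = t * B;
    if (train) w.Hprev.cols(c0, c0 + B - 1) = w.h.cols(0, B - 1);
    w.Gt.cols(0, B - 1) = Wh * w.h.cols(0, B - 1);  // recurrent contribution
    for (uword j = 0; j < B; ++j) {
      real_t* g = w.G.colptr(c0 + j);
      const real_t* r = w.Gt.colptr(j);
      real_t* cc = w.c.colptr(j);
      real_t* hh = w.h.colptr(j);
      real_t* Ccol = w.C.colptr(c0 + j);
      real_t* TCcol = w.TC.colptr(c0 + j);
      real_t* Hcol = w.Hout.colptr(c0 + j);
      for (uword u = 0; u < H; ++u) {
        const real_t f = sigmoid1(g[u] + r[u]);
        const real_t i = sigmoid1(g[H + u] + r[H + u]);
        const real_t gg = std::tanh(g[2 * H + u] + r[2 * H + u]);
        const real_t o = sigmoid1(g[3 * H + u] + r[3 * H + u]);
        const real_t cn = f * cc[u] + i * gg;
        const real_t tc = std::tanh(cn);
        const real_t hn = o * tc;
        cc[u] = cn; hh[u] = hn;
        if (train) {
          g[u] = f; g[H + u] = i; g[2 * H + u] = gg; g[3 * H + u] = o;
          Ccol[u] = cn; TCcol[u] = tc;
        }
        Hcol[u] = hn;
      }
    }
  }
}

// Backward through one layer. dH (H x BL) holds the gradient w.r.t. the
// layer's pre-dropout hidden outputs; on return dW/db are filled and dX
// (Din x BL) receives the gradient w.r.t. the layer input.
static void layer_backward(const wmat& W, const wmat& X, const wmat& dH,
                           uword B, uword L, LayerWork& w,
                           wmat& dW, wvec& db, wmat& dX, bool want_dX) {
  const uword H = W.n_rows / 4;
  const uword Din = W.n_cols - H;
  const wmat Wh = W.cols(0, H - 1);
  const wmat Wx = W.cols(H, H + Din - 1);
  const uword BL = B * L;

  w.dh.zeros(); w.dc.zeros();
  for (uword t = L; t-- > 0;) {
    const uword c0 = t * B;
    for (uword j = 0; j < B; ++j) {
      const real_t* g = w.G.colptr(c0 + j);
      const real_t* tc = w.TC.colptr(c0 + j);
      const real_t* cprev = (t > 0) ? w.C.colptr(c0 - B + j) : nullptr;
      const real_t* dtop = dH.colptr(c0 + j);
      real_t* dhj = w.dh.colptr(j);
      real_t* dcj = w.dc.colptr(j);
      real_t* DGj = w.DG.colptr(c0 + j);
      for (uword u = 0; u < H; ++u) {
        const real_t f = g[u], i = g[H + u], gg = g[2 * H + u],
                     o = g[3 * H + u];
        const real_t dh_u = dtop[u] + dhj[u];
        const real_t dc_u = dcj[u] + dh_u * o * (1.0f - tc[u] * tc[u]);
        const real_t cp = cprev ? cprev[u] : 0.0f;
        DGj[u] = dc_u * cp * f * (1.0f - f);
        DGj[H + u] = dc_u * gg * i * (1.0f - i);
        DGj[2 * H + u] = dc_u * i * (1.0f - gg * gg);
        DGj[3 * H + u] = dh_u * tc[u] * o * (1.0f - o);
        dcj[u] = dc_u * f;
      }
    }
    w.dh.cols(0, B - 1) = Wh.t() * w.DG.cols(c0, c0 + B - 1);
  }
  const wmat& DG = w.DG;
  dW.cols(0, H - 1) = DG.cols(0, BL - 1) * w.Hprev.cols(0, BL - 1).t();
  dW.cols(H, H + Din - 1) = DG.cols(0, BL - 1) * X.t();
  db = arma::sum(DG.cols(0, BL - 1), 1);
  if (want_dX) dX = Wx.t() * DG.cols(0, BL - 1);
}

struct AdamState {
  wmat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
  void step(wmat& W, const wmat& g, real_t lr, real_t b1, real_t b2,
            real_t eps, long t) {
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * (g % g);
    const real_t c1 = 1.0f - std::pow(b1, static_cast<real_t>(t));
    const real_t c2 = 1.0f - std::pow(b2, static_cast<real_t>(t));
    W -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

// Gather sequences `ids` of cube X (D x L x S) into a (D x B*L) block with
// column t*B + b = X(:, t, ids[b]).
static void gather_block(const wcube& X, const std::vector<uword>& ids,
                         uword L, wmat& out) {
  const uword D = X.n_rows, B = ids.size();
  for (uword b = 0; b < B; ++b) {
    const wmat& sl = X.slice(ids[b]);
    for (uword t = 0; t < L; ++t) {
      std::copy(sl.colptr(t), sl.colptr(t) + D, out.colptr(t * B + b));
    }
  }
}

// [[Rcpp::export]]
List cpp_lstm_train(List Wlist, List blist, arma::mat W_out0,
                    arma::vec b_out0, arma::cube X0, arma::cube Y0,
                    double lr, int epochs, double dropout, int batch,
                    int seed, double beta1, double beta2, double eps) {
  const uword n_layers = Wlist.size();
  const wcube X = arma::conv_to<wcube>::from(X0);
  const wcube Y = arma::conv_to<wcube>::from(Y0);
  wmat W_out = arma::conv_to<wmat>::from(W_out0);
  wvec b_out = arma::conv_to<wvec>::from(b_out0);
  const uword L = X.n_cols;
  const uword S = X.n_slices;
  const uword D = X.n_rows;
  const uword out_dim = W_out.n_rows;
  const uword Bmax = std::min<uword>(batch, S);
  const real_t lrf = lr, b1f = beta1, b2f = beta2, epsf = eps;

  std::vector<wmat> W(n_layers);
  std::vector<wvec> b(n_layers);
  std::vector<uword> Hsz(n_layers);
  for (uword l = 0; l < n_layers; ++l) {
    W[l] = arma::conv_to<wmat>::from(as<mat>(Wlist[l]));
    b[l] = arma::conv_to<wvec>::from(as<vec>(blist[l]));
    Hsz[l] = W[l].n_rows / 4;
  }

  std::vector<AdamState> aW(n_layers), ab(n_layers);
  std::vector<wmat> dWl(n_layers);
  std::vector<wvec> dbl(n_layers);
  for (uword l = 0; l < n_layers; ++l) {
    aW[l].init(W[l].n_rows, W[l].n_cols);
    ab[l].init(b[l].n_elem, 1);
    dWl[l].set_size(W[l].n_rows, W[l].n_cols);
  }
  AdamState aWo, abo;
  aWo.init(W_out.n_rows, W_out.n_cols);
  abo.init(b_out.n_elem, 1);

  const bool use_dropout = dropout > 0.0 && n_layers > 1;
  const real_t keep = 1.0f - static_cast<real_t>(dropout);
  std::vector<LayerWork> work(n_layers);
  for (uword l = 0; l < n_layers; ++l) {
    work[l].init(Hsz[l], Bmax * L, Bmax, use_dropout && l + 1 < n_layers);
  }
  wmat Xb(D, Bmax * L), Yb(out_dim, Bmax * L);
  wmat dX;  // gradient buffer between layers

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<uword> order(S);
  for (uword s = 0; s < S; ++s) order[s] = s;

  vec loss_trace(epochs, arma::fill::zeros);
  long t_adam = 0;
  int diverged = -1;

  for (int ep = 0; ep < epochs && diverged < 0; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (uword start = 0; start < S; start += Bmax) {
      const uword B = std::min<uword>(Bmax, S - start);
      const uword BL = B * L;
      std::vector<uword> ids(order.begin() + start,
                             order.begin() + start + B);
      wmat Xv(Xb.memptr(), D, BL, false, true);
      wmat Yv(Yb.memptr(), out_dim, BL, false, true);
      gather_block(X, ids, L, Xv);
      gather_block(Y, ids, L, Yv);

      const wmat* cur = &Xv;
      std::vector<wmat> views;  // non-owning views of layer outputs
      views.reserve(n_layers);
      for (uword l = 0; l < n_layers; ++l) {
        layer_forward(W[l], b[l], *cur, B, L, true, work[l]);
        if (use_dropout && l + 1 < n_layers) {
          real_t* hp = work[l].Hout.memptr();
          real_t* mp = work[l].mask.memptr();
          const uword n = Hsz[l] * BL;
          for (uword k = 0; k < n; ++k) {
            const real_t m = (unif(rng) < keep) ? (1.0f / keep) : 0.0f;
            mp[k] = m;
            hp[k] *= m;  // Hout becomes the dropped input of the next layer
          }
        }
        views.emplace_back(work[l].Hout.memptr(), Hsz[l], BL, false, true);
        cur = &views.back();
      }
      wmat Yp = W_out * (*cur);
      Yp.each_col() += b_out;
      Yp -= Yv;                      // Yp now holds the residual E
      const double batch_sse = arma::accu(arma::conv_to<mat>::from(Yp % Yp));
      sse += batch_sse;
      if (!std::isfinite(batch_sse)) { diverged = ep; break; }

      Yp *= 2.0f / static_cast<real_t>(Yp.n_elem);   // dY
      wmat dWo = Yp * cur->t();
      wvec dbo = arma::sum(Yp, 1);
      wmat dH = W_out.t() * Yp;

      for (uword l = n_layers; l-- > 0;) {
        const wmat& Xin = (l == 0) ? Xv : views[l - 1];
        layer_backward(W[l], Xin, dH, B, L, work[l],
                       dWl[l], dbl[l], dX, l > 0);
        if (l > 0) {
          if (use_dropout) dX %= work[l - 1].mask.cols(0, BL - 1);
          dH = std::move(dX);
        }
      }

      ++t_adam;
      for (uword l = 0; l < n_layers; ++l) {
        aW[l].step(W[l], dWl[l], lrf, b1f, b2f, epsf, t_adam);
        wmat bm(b[l].memptr(), b[l].n_elem, 1, false, true);
        const wmat gb(dbl[l].memptr(), dbl[l].n_elem, 1, false, true);
        ab[l].step(bm, gb, lrf, b1f, b2f, epsf, t_adam);
      }
      aWo.step(W_out, dWo, lrf, b1f, b2f, epsf, t_adam);
      wmat bo(b_out.memptr(), b_out.n_elem, 1, false, true);
      const wmat gbo(dbo.memptr(), dbo.n_elem, 1, false, true);
      abo.step(bo, gbo, lrf, b1f, b2f, epsf, t_adam);
    }
    loss_trace(ep) = sse / static_cast<double>(S * L * out_dim);
  }

  List Wres(n_layers), bres(n_layers);
  for (uword l = 0; l < n_layers; ++l) {
    Wres[l] = arma::conv_to<mat>::from(W[l]);
    bres[l] = arma::conv_to<vec>::from(b[l]);
  }
  return List::create(
    _["W"] = Wres, _["b"] = bres,
    _["W_out"] = arma::conv_to<mat>::from(W_out),
    _["b_out"] = arma::conv_to<vec>::from(b_out),
    _["loss"] = loss_trace, _["diverged"] = diverged
  );
}

// [[Rcpp::export]]
arma::cube cpp_lstm_forward(List Wlist, List blist, arma::mat W_out0,
                            arma::vec b_out0, arma::cube X0) {
  const uword n_layers = Wlist.size();
  const wcube X = arma::conv_to<wcube>::from(X0);
  const wmat W_out = arma::conv_to<wmat>::from(W_out0);
  const wvec b_out = arma::conv_to<wvec>::from(b_out0);
  const uword L = X.n_cols;
  const uword S = X.n_slices;
  const uword D = X.n_rows;

  std::vector<uword> ids(S);
  for (uword s = 0; s < S; ++s) ids[s] = s;
  wmat cur(D, S * L);
  gather_block(X, ids, L, cur);
  for (uword l = 0; l < n_layers; ++l) {
    const wmat W = arma::conv_to<wmat>::from(as<mat>(Wlist[l]));
    const wvec b = arma::conv_to<wvec>::from(as<vec>(blist[l]));
    LayerWork w;
    const uword H = W.n_rows / 4;
    // eval pass: gates/caches unused, but the buffers must exist
    w.init(H, S * L, S, false);
    layer_forward(W, b, cur, S, L, false, w);
    cur = w.Hout;
  }
  wmat Yp = W_out * cur;
  Yp.each_col() += b_out;

  cube out(W_out.n_rows, L, S);
  for (uword s = 0; s < S; ++s) {
    for (uword t = 0; t < L; ++t) {
      out.slice(s).col(t) = arma::conv_to<vec>::from(Yp.col(t * S + s));
    }
  }
  return out;
}
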