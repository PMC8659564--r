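// Minibatch Adam trainer for the stateless MLP baseline
// (input -> tanh hidden -> linear output, MSE loss). Single precision, like
// the LSTM backend; shuffling driven by one seeded mt19937_64.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uword;

namespace {

using wmat = arma::fmat;
using wvec = arma::fvec;
typedef float real_t;

struct Adam {
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

}  // namespace

// [[Rcpp::export]]
List cpp_mlp_train(arma::mat W1_0, arma::vec b1_0, arma::mat W2_0,
                   arma::vec b2_0, arma::mat X0, arma::mat Y0,
                   double lr, int epochs, int batch, int seed,
                   double beta1, double beta2, double eps) {
  const wmat X = arma::conv_to<wmat>::from(X0);
  const wmat Y = arma::conv_to<wmat>::from(Y0);
  wmat W1 = arma::conv_to<wmat>::from(W1_0);
  wvec b1 = arma::conv_to<wvec>::from(b1_0);
  wmat W2 = arma::conv_to<wmat>::from(W2_0);
  wvec b2 = arma::conv_to<wvec>::from(b2_0);
  const uword M = X.n_cols;
  const uword D = X.n_rows;
  const uword out_dim = Y.n_rows;
  const uword Bmax = std::min<uword>(batch, M);
  const real_t lrf = lr, b1f = beta1, b2f = beta2, epsf = eps;

  Adam aW1, ab1, aW2, ab2;
  aW1.init(W1.n_rows, W1.n_cols);
  ab1.init(b1.n_elem, 1);
  aW2.init(W2.n_rows, W2.n_cols);
  ab2.init(b2.n_elem, 1);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<uword> order(M);
  for (uword i = 0; i < M; ++i) order[i] = i;

  wmat Xb(D, Bmax), Yb(out_dim, Bmax);
  arma::vec loss_trace(epochs, arma::fill::zeros);
  long t_adam = 0;
  int diverged = -1;

  for (int ep = 0; ep < epochs && diverged < 0; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (uword start = 0; start < M; start += Bmax) {
      const uword B = std::min<uword>(Bmax, M - start);
      for (uword j = 0; j < B; ++j) {
        const uword c = order[start + j];
        std::copy(X.colptr(c), X.colptr(c) + D, Xb.colptr(j));
        std::copy(Y.colptr(c), Y.colptr(c) + out_dim, Yb.colptr(j));
      }
      wmat H1 = W1 * Xb.cols(0, B - 1);
      H1.each_col() += b1;
      H1 = arma::tanh(H1);
      wmat E = W2 * H1;
      E.each_col() += b2;
      E -= Yb.cols(0, B - 1);
      const double batch_sse = arma::accu(arma::conv_to<arma::mat>::from(E % E));
      sse += batch_sse;
      if (!std::isfinite(batch_sse)) { diverged = ep; break; }

      E *= 2.0f / static_cast<real_t>(E.n_elem);     // dY
      wmat dW2 = E * H1.t();
      wvec db2 = arma::sum(E, 1);
      wmat dH = (W2.t() * E) % (1.0f - H1 % H1);
      wmat dW1 = dH * Xb.cols(0, B - 1).t();
      wvec db1 = arma::sum(dH, 1);

      ++t_adam;
      aW1.step(W1, dW1, lrf, b1f, b2f, epsf, t_adam);
      wmat b1m(b1.memptr(), b1.n_elem, 1, false, true);
      const wmat g1(db1.memptr(), db1.n_elem, 1, false, true);
      ab1.step(b1m, g1, lrf, b1f, b2f, epsf, t_adam);
      aW2.step(W2, dW2, lrf, b1f, b2f, epsf, t_adam);
      wmat b2m(b2.memptr(), b2.n_elem, 1, false, true);
      const wmat g2(db2.memptr(), db2.n_elem, 1, false, true);
      ab2.step(b2m, g2, lrf, b1f, b2f, epsf, t_adam);
    }
    loss_trace(ep) = sse / static_cast<double>(M * out_dim);
  }

  return List::create(
    _["W1"] = arma::conv_to<arma::mat>::from(W1),
    _["b1"] = arma::conv_to<arma::vec>::from(b1),
    _["W2"] = arma::conv_to<arma::mat>::from(W2),
    _["b2"] = arma::conv_to<arma::vec>::from(b2),
    _["loss"] = loss_trace, _["diverged"] = diverged
  );
}
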