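// Small univariate LSTM forecaster: one LSTM layer, a dropout layer on the
// final hidden state, and a dense linear head. Trained with Adam on MSE.
// The network is deliberately minimal (input dimension 1, short look-back
// windows, a few hundred samples at most), so everything is dense algebra.
//
// All randomness (weight initialisation, per-epoch shuffling, dropout masks,
// MC-dropout inference) flows from a private mt19937_64 stream with manually
// coded uniform/normal draws, so a seed fully determines training and
// forecasts, bit for bit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  // uniform on [0, 1) with 53-bit resolution
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_range(double lo, double hi) { return lo + (hi - lo) * unif(); }
  int below(int n) { return static_cast<int>(eng() % static_cast<uint64_t>(n)); }
};

struct Weights {
  arma::vec W;    // input kernel, 4H (input dim is 1)
  arma::mat U;    // recurrent kernel, 4H x H
  arma::vec b;    // bias, 4H
  arma::vec wd;   // dense kernel, H
  double bd;      // dense bias
};

// Gate row layout within the stacked 4H dimension: [i; f; g; o].
inline arma::mat sigmoid(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

Weights init_weights(int H, Rng& rng) {
  Weights w;
  double lim_W = std::sqrt(6.0 / (1 + 4 * H));
  double lim_U = std::sqrt(6.0 / (H + 4 * H));
  double lim_d = std::sqrt(6.0 / (H + 1));
  w.W.set_size(4 * H);
  for (auto& v : w.W) v = rng.unif_range(-lim_W, lim_W);
  w.U.set_size(4 * H, H);
  for (auto& v : w.U) v = rng.unif_range(-lim_U, lim_U);
  w.b = arma::zeros(4 * H);
  w.b.subvec(H, 2 * H - 1).fill(1.0);   // forget-gate bias starts open
  w.wd.set_size(H);
  for (auto& v : w.wd) v = rng.unif_range(-lim_d, lim_d);
  w.bd = 0.0;
  return w;
}

struct Cache {
  std::vector<arma::mat> i, f, g, o, c, tc, h;  // per timestep, H x B
};

// Forward over L timesteps for a batch; X_batch is L x B (inputs over time).
arma::rowvec forward(const Weights& w, int H, const arma::mat& X_batch,
                     Cache* cache, const arma::mat* drop_mask,
                     arma::mat* h_last, arma::mat* h_drop) {
  int L = X_batch.n_rows, B = X_batch.n_cols;
  arma::mat h = arma::zeros(H, B), c = arma::zeros(H, B);
  for (int t = 0; t < L; ++t) {
    arma::mat z = w.W * X_batch.row(t) + w.U * h;   // 4H x B
    z.each_col() += w.b;
    arma::mat i = sigmoid(z.rows(0, H - 1));
    arma::mat f = sigmoid(z.rows(H, 2 * H - 1));
    arma::mat g = arma::tanh(z.rows(2 * H, 3 * H - 1));
    arma::mat o = sigmoid(z.rows(3 * H, 4 * H - 1));
    arma::mat c_new = f % c + i % g;
    arma::mat tc = arma::tanh(c_new);
    arma::mat h_new = o % tc;
    if (cache) {
      cache->i.push_back(i); cache->f.push_back(f); cache->g.push_back(g);
      cache->o.push_back(o); cache->c.push_back(c); cache->tc.push_back(tc);
      cache->h.push_back(h);
    }
    h = h_new; c = c_new;
  }
  arma::mat hd = drop_mask ? arma::mat(h % (*drop_mask)) : h;
  if (h_last) *h_last = h;
  if (h_drop) *h_drop = hd;
  return w.wd.t() * hd + w.bd;
}

struct Adam {
  arma::vec mW, vW, mb, vb, mwd, vwd;
  arma::mat mU, vU;
  double mbd = 0, vbd = 0;
  long step = 0;
  explicit Adam(int H)
      : mW(arma::zeros(4 * H)), vW(arma::zeros(4 * H)),
        mb(arma::zeros(4 * H)), vb(arma::zeros(4 * H)),
        mwd(arma::zeros(H)), vwd(arma::zeros(H)),
        mU(arma::zeros(4 * H, H)), vU(arma::zeros(4 * H, H)) {}
  template <typename T>
  void upd(T& param, T& m, T& v, const T& grad, double lr, double bc1,
           double bc2) {
    m = 0.9 * m + 0.1 * grad;
    v = 0.999 * v + 0.001 * (grad % grad);
    param -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-7);
  }
  void upd_scalar(double& param, double& m, double& v, double grad, double lr,
                  double bc1, double bc2) {
    m = 0.9 * m + 0.1 * grad;
    v = 0.999 * v + 0.001 * grad * grad;
    param -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-7);
  }
};

}  // namespace

// Train on supervised pairs. X: n x L window matrix (scaled), y: n targets.
// Returns the trained weights plus the final-epoch training MSE.
// [[Rcpp::export]]
List cpp_lstm_train(const arma::mat& X, const arma::vec& y, int units,
                    double dropout, double lr, int epochs, int batch_size,
                    double seed) {
  int n = X.n_rows, L = X.n_cols, H = units;
  if (n < 2) stop("need at least 2 training pairs");
  if (batch_size < 1) batch_size = 1;
  Rng rng(static_cast<uint64_t>(seed));
  Weights w = init_weights(H, rng);
  Adam adam(H);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double last_mse = NA_REAL;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the private stream
    for (int i = n - 1; i > 0; --i) std::swap(idx[i], idx[rng.below(i + 1)]);
    double ep_sse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      arma::mat Xb(L, B);
      arma::rowvec yb(B);
      for (int k = 0; k < B; ++k) {
        Xb.col(k) = X.row(idx[start + k]).t();
        yb(k) = y(idx[start + k]);
      }
      arma::mat mask(H, B, arma::fill::ones);
      if (dropout > 0) {
        for (auto& v : mask) v = (rng.unif() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      }
      Cache cache;
      arma::mat h_last, h_drop;
      arma::rowvec yhat = forward(w, H, Xb, &cache, &mask, &h_last, &h_drop);
      arma::rowvec err = yhat - yb;
      ep_sse += arma::accu(err % err);
      arma::rowvec dy = 2.0 * err / B;
      // dense head
      arma::vec g_wd = h_drop * dy.t();
      double g_bd = arma::accu(dy);
      arma::mat dh = (w.wd * dy) % mask;  // back through dropout
      arma::mat dc = arma::zeros(H, B);
      arma::vec g_W = arma::zeros(4 * H), g_b = arma::zeros(4 * H);
      arma::mat g_U = arma::zeros(4 * H, H);
      for (int t = L - 1; t >= 0; --t) {
        const arma::mat& i = cache.i[t];
        const arma::mat& f = cache.f[t];
        const arma::mat& g = cache.g[t];
        const arma::mat& o = cache.o[t];
        const arma::mat& c_prev = cache.c[t];
        const arma::mat& tc = cache.tc[t];
        arma::mat dz(4 * H, B);
        arma::mat d_o = dh % tc;
        dc += dh % o % (1.0 - tc % tc);
        arma::mat d_i = dc % g;
        arma::mat d_f = dc % c_prev;
        arma::mat d_g = dc % i;
        dz.rows(0, H - 1) = d_i % i % (1.0 - i);
        dz.rows(H, 2 * H - 1) = d_f % f % (1.0 - f);
        dz.rows(2 * H, 3 * H - 1) = d_g % (1.0 - g % g);
        dz.rows(3 * H, 4 * H - 1) = d_o % o % (1.0 - o);
        g_W += dz * Xb.row(t).t();
        g_U += dz * cache.h[t].t();
        g_b += arma::sum(dz, 1);
        dh = w.U.t() * dz;
        dc = dc % f;
      }
      adam.step += 1;
      double bc1 = 1.0 - std::pow(0.9, adam.step);
      double bc2 = 1.0 - std::pow(0.999, adam.step);
      adam.upd(w.W, adam.mW, adam.vW, g_W, lr, bc1, bc2);
      adam.upd(w.U, adam.mU, adam.vU, g_U, lr, bc1, bc2);
      adam.upd(w.b, adam.mb, adam.vb, g_b, lr, bc1, bc2);
      adam.upd(w.wd, adam.mwd, adam.vwd, g_wd, lr, bc1, bc2);
      adam.upd_scalar(w.bd, adam.mbd, adam.vbd, g_bd, lr, bc1, bc2);
    }
    last_mse = ep_sse / n;
  }
  return List::create(_["W"] = w.W, _["U"] = w.U, _["b"] = w.b,
                      _["wd"] = w.wd, _["bd"] = w.bd, _["units"] = H,
                      _["train_mse"] = last_mse);
}

// Recursive h-step forecasting from the last look-back window (scaled space).
// With use_dropout, each pass draws fresh inverted-dropout masks per step
// (MC dropout); otherwise all passes are identical deterministic forecasts.
// Returns an n_passes x h matrix.
// [[Rcpp::export]]
arma::mat cpp_lstm_forecast(const List& weights, const arma::vec& window,
                            int h, double dropout, bool use_dropout,
                            int n_passes, double seed) {
  if (h < 1) stop("h must be >= 1");
  if (n_passes < 1) stop("n_passes must be >= 1");
  Weights w;
  w.W = as<arma::vec>(weights["W"]);
  w.U = as<arma::mat>(weights["U"]);
  w.b = as<arma::vec>(weights["b"]);
  w.wd = as<arma::vec>(weights["wd"]);
  w.bd = as<double>(weights["bd"]);
  int H = as<int>(weights["units"]);
  int L = window.n_elem;
  Rng rng(static_cast<uint64_t>(seed));
  arma::mat out(n_passes, h);
  for (int pass = 0; pass < n_passes; ++pass) {
    arma::vec win = window;
    for (int step = 0; step < h; ++step) {
      arma::mat Xb(L, 1);
      Xb.col(0) = win;
      arma::mat mask(H, 1, arma::fill::ones);
      if (use_dropout && dropout > 0) {
        for (auto& v : mask)
          v = (rng.unif() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      }
      arma::rowvec yhat = forward(w, H, Xb, nullptr, &mask, nullptr, nullptr);
      double pred = yhat(0);
      out(pass, step) = pred;
      if (L > 1) win.subvec(0, L - 2) = win.subvec(1, L - 1);
      win(L - 1) = pred;
    }
  }
  return out;
}
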