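// DQN training core: feedforward Q-network (5 -> 64 -> 64 -> 201, ReLU),
// mean-squared TD error, Adam, FIFO replay with uniform batch sampling,
// epsilon-greedy exploration with linear decay, periodic target-network
// sync.  Kept in C++ so a desk-scale training run (~10^5-10^6 env steps)
// stays within minutes on one CPU.  All randomness flows from one
// std::mt19937 seed; single-threaded and deterministic on a fixed platform.

#include <RcppArmadillo.h>
#include <random>
#include <unordered_set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Net {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
};

Net net_from_list(const List& l) {
  Net n;
  n.W1 = as<mat>(l["W1"]);
  n.b1 = as<rowvec>(l["b1"]);
  n.W2 = as<mat>(l["W2"]);
  n.b2 = as<rowvec>(l["b2"]);
  n.W3 = as<mat>(l["W3"]);
  n.b3 = as<rowvec>(l["b3"]);
  return n;
}

List net_to_list(const Net& n) {
  return List::create(_["W1"] = n.W1, _["b1"] = n.b1, _["W2"] = n.W2,
                      _["b2"] = n.b2, _["W3"] = n.W3, _["b3"] = n.b3);
}

Net net_zeros_like(const Net& n) {
  Net z;
  z.W1.zeros(arma::size(n.W1));
  z.b1.zeros(n.b1.n_elem);
  z.W2.zeros(arma::size(n.W2));
  z.b2.zeros(n.b2.n_elem);
  z.W3.zeros(arma::size(n.W3));
  z.b3.zeros(n.b3.n_elem);
  return z;
}

inline void relu_inplace(mat& X) { X.elem(arma::find(X < 0)).zeros(); }

// batch forward keeping hidden activations for backprop
mat forward(const Net& n, const mat& X, mat& H1, mat& H2) {
  H1 = X * n.W1;
  H1.each_row() += n.b1;
  relu_inplace(H1);
  H2 = H1 * n.W2;
  H2.each_row() += n.b2;
  relu_inplace(H2);
  mat Q = H2 * n.W3;
  Q.each_row() += n.b3;
  return Q;
}

rowvec forward1(const Net& n, const rowvec& x) {
  rowvec h1 = x * n.W1 + n.b1;
  h1.elem(arma::find(h1 < 0)).zeros();
  rowvec h2 = h1 * n.W2 + n.b2;
  h2.elem(arma::find(h2 < 0)).zeros();
  return h2 * n.W3 + n.b3;
}

struct Adam {
  Net m, v;
  long t = 0;
  static constexpr double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  explicit Adam(const Net& n) : m(net_zeros_like(n)), v(net_zeros_like(n)) {}

  template <typename T>
  void step_one(T& p, T& mm, T& vv, const T& g, double lr, double c1,
                double c2) {
    mm = beta1 * mm + (1 - beta1) * g;
    vv = beta2 * vv + (1 - beta2) * (g % g);
    p -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }

  void step(Net& net, const Net& g, double lr) {
    ++t;
    const double c1 = 1 - std::pow(beta1, (double)t);
    const double c2 = 1 - std::pow(beta2, (double)t);
    step_one(net.W1, m.W1, v.W1, g.W1, lr, c1, c2);
    step_one(net.b1, m.b1, v.b1, g.b1, lr, c1, c2);
    step_one(net.W2, m.W2, v.W2, g.W2, lr, c1, c2);
    step_one(net.b2, m.b2, v.b2, g.b2, lr, c1, c2);
    step_one(net.W3, m.W3, v.W3, g.W3, lr, c1, c2);
    step_one(net.b3, m.b3, v.b3, g.b3, lr, c1, c2);
  }

  List to_list() const {
    return List::create(_["m"] = net_to_list(m), _["v"] = net_to_list(v),
                        _["t"] = (double)t);
  }

  static Adam from_list(const List& l, const Net& like) {
    Adam a(like);
    a.m = net_from_list(l["m"]);
    a.v = net_from_list(l["v"]);
    a.t = (long)as<double>(l["t"]);
    return a;
  }
};

// one gradient step of Q(s,a) toward r + gamma * max_a' Q_target(s', a');
// terminal transitions regress toward r alone; returns mean squared TD error
double td_update_inner(Net& net, const Net& target, Adam& adam, const mat& S,
                       const arma::ivec& A, const vec& R, const mat& S2,
                       const arma::ivec& done, double gamma, double lr) {
  const arma::uword n = S.n_rows;
  // online hidden activations; the output layer is only needed at the
  // taken action, so Q(i, A[i]) is a single dot product per row and the
  // loss gradient dQ has exactly one nonzero per row -- the three
  // 201-wide GEMMs of a dense backprop collapse to scatters
  mat H1 = S * net.W1;
  H1.each_row() += net.b1;
  relu_inplace(H1);
  mat H2 = H1 * net.W2;
  H2.each_row() += net.b2;
  relu_inplace(H2);

  mat H1t, H2t;
  mat Qt = forward(target, S2, H1t, H2t);  // full: max over actions needed

  Net g;
  g.W3.zeros(arma::size(net.W3));
  g.b3.zeros(net.b3.n_elem);
  mat dH2(arma::size(H2), arma::fill::none);
  double loss = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword a = (arma::uword)A[i];
    const double q_sa = arma::dot(H2.row(i), net.W3.col(a)) + net.b3[a];
    double y = R[i];
    if (!done[i]) y += gamma * Qt.row(i).max();
    const double diff = q_sa - y;
    loss += diff * diff;
    const double dq = 2.0 * diff / (double)n;
    g.W3.col(a) += dq * H2.row(i).t();
    g.b3[a] += dq;
    dH2.row(i) = dq * net.W3.col(a).t();
  }
  loss /= (double)n;

  dH2.elem(arma::find(H2 <= 0)).zeros();
  g.W2 = H1.t() * dH2;
  g.b2 = arma::sum(dH2, 0);
  mat dH1 = dH2 * net.W2.t();
  dH1.elem(arma::find(H1 <= 0)).zeros();
  g.W1 = S.t() * dH1;
  g.b1 = arma::sum(dH1, 0);

  adam.step(net, g, lr);
  return loss;
}

// Floyd's algorithm: k distinct uniform draws from {0, ..., n-1}
void sample_without_replacement(std::mt19937& rng, int n, int k,
                                std::vector<int>& out) {
  out.clear();
  std::unordered_set<int> seen;
  for (int j = n - k; j < n; ++j) {
    std::uniform_int_distribution<int> d(0, j);
    int t = d(rng);
    if (seen.count(t)) t = j;
    seen.insert(t);
    out.push_back(t);
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".td_update_cpp")]]
List td_update_cpp(List params, List target_params, SEXP adam_state,
                   arma::mat S, arma::ivec A, arma::vec R, arma::mat S2,
                   arma::ivec done, double gamma, double lr) {
  Net net = net_from_list(params);
  Net target = net_from_list(target_params);
  Adam adam = Rf_isNull(adam_state) ? Adam(net)
                                    : Adam::from_list(List(adam_state), net);
  double loss = td_update_inner(net, target, adam, S, A, R, S2, done, gamma,
                                lr);
  return List::create(_["net"] = net_to_list(net),
                      _["opt_state"] = adam.to_list(), _["loss"] = loss);
}

//' @noRd
// [[Rcpp::export(name = ".dqn_train_cpp")]]
List dqn_train_cpp(List states, List gt, arma::vec rmr_sec, List win_starts,
                   int window_len, List init_params, double lr, double gamma,
                   int capacity, int batch, int warmup, int update_every,
                   int target_sync, double eps_start, double eps_end,
                   double eps_frac, int epochs, int seed) {
  const int n_sessions = states.size();
  std::vector<mat> S(n_sessions);
  std::vector<vec> G(n_sessions);
  std::vector<std::vector<int>> W(n_sessions);
  long steps_per_epoch = 0;
  for (int i = 0; i < n_sessions; ++i) {
    S[i] = as<mat>(states[i]);
    G[i] = as<vec>(gt[i]);
    IntegerVector w = win_starts[i];
    W[i] = std::vector<int>(w.begin(), w.end());
    steps_per_epoch += (long)W[i].size() * window_len;
  }
  const int state_dim = n_sessions > 0 ? (int)S[0].n_cols : 0;
  const int n_actions = as<mat>(init_params["W3"]).n_cols;

  Net net = net_from_list(init_params);
  Net target = net;
  Adam adam(net);
  std::mt19937 rng((unsigned int)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::uniform_int_distribution<int> rand_action(0, n_actions - 1);

  // FIFO replay: circular overwrite of the oldest entry
  mat BS(capacity, state_dim), BS2(capacity, state_dim);
  arma::ivec BA(capacity), BD(capacity);
  vec BR(capacity);
  int pos = 0, size = 0;

  const double total_steps = (double)steps_per_epoch * epochs;
  const double anneal_steps = std::max(1.0, eps_frac * total_steps);
  long step = 0, n_updates = 0;
  std::vector<double> loss_hist(epochs, NA_REAL);
  std::vector<double> reward_hist(epochs, NA_REAL);
  std::vector<int> idx;
  mat bS(batch, state_dim), bS2(batch, state_dim);
  arma::ivec bA(batch), bD(batch);
  vec bR(batch);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0, reward_sum = 0.0;
    long loss_n = 0, reward_n = 0;
    for (int si = 0; si < n_sessions; ++si) {
      const double rmr = rmr_sec[si];
      for (int ws : W[si]) {
        for (int t = 0; t < window_len; ++t) {
          const int row = ws + t;
          const rowvec state = S[si].row(row);
          const double frac = std::min(1.0, (double)step / anneal_steps);
          const double eps = eps_start + (eps_end - eps_start) * frac;
          int a;
          if (unif01(rng) < eps) {
            a = rand_action(rng);
          } else {
            a = (int)forward1(net, state).index_max();  // first max on ties
          }
          const double pred = rmr * (1.0 + a / 10.0);
          const double g = G[si][row];
          const double r = -std::fabs(g - pred) / (1.0 + g);
          const bool dn = (t == window_len - 1);

          BS.row(pos) = state;
          BS2.row(pos) = dn ? state : S[si].row(row + 1);
          BA[pos] = a;
          BR[pos] = r;
          BD[pos] = dn ? 1 : 0;
          pos = (pos + 1) % capacity;
          if (size < capacity) ++size;

          ++step;
          reward_sum += r;
          ++reward_n;

          if (size >= warmup && step % update_every == 0) {
            sample_without_replacement(rng, size, std::min(batch, size), idx);
            const int nb = (int)idx.size();
            for (int k = 0; k < nb; ++k) {
              bS.row(k) = BS.row(idx[k]);
              bS2.row(k) = BS2.row(idx[k]);
              bA[k] = BA[idx[k]];
              bR[k] = BR[idx[k]];
              bD[k] = BD[idx[k]];
            }
            loss_sum += td_update_inner(net, target, adam, bS.rows(0, nb - 1),
                                        bA.subvec(0, nb - 1),
                                        bR.subvec(0, nb - 1),
                                        bS2.rows(0, nb - 1),
                                        bD.subvec(0, nb - 1), gamma, lr);
            ++loss_n;
            ++n_updates;
            if (n_updates % target_sync == 0) target = net;
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
    if (loss_n > 0) loss_hist[ep] = loss_sum / loss_n;
    if (reward_n > 0) reward_hist[ep] = reward_sum / reward_n;
  }

  return List::create(_["net"] = net_to_list(net),
                      _["loss_by_epoch"] = wrap(loss_hist),
                      _["mean_reward_by_epoch"] = wrap(reward_hist),
                      _["n_env_steps"] = (double)step,
                      _["n_updates"] = (double)n_updates);
}
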