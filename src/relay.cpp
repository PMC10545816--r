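// Core numerical kernels: brute-force kNN with deterministic tie-breaks and
// the per-gene relay-velocity trainer (2-100-100-3 MLP, leaky-ReLU hidden
// layers, sigmoid-squashed rate outputs, Adam with L2 weight decay, hard-max
// cosine loss against neighbor displacements).
//
// All randomness (weight init, per-epoch cell subsets) is drawn from R's RNG
// so results are reproducible from set.seed() and independent of the worker
// count used to parallelize over genes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact k-nearest neighbors by scanning all pairs. Ties in distance are
// broken by the lower cell index. Self is excluded. Returns 1-based indices.
// [[Rcpp::export]]
arma::imat knn_brute_cpp(const arma::mat& X, const int k) {
  const int n = X.n_rows;
  arma::imat out(n, k);
  std::vector<std::pair<double, int>> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = 0.0;
      for (unsigned int c = 0; c < X.n_cols; ++c) {
        const double diff = X(i, c) - X(j, c);
        d += diff * diff;
      }
      cand[m++] = std::make_pair(d, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int l = 0; l < k; ++l) out(i, l) = cand[l].second + 1;
  }
  return out;
}

namespace {

struct Net {
  arma::mat W1, W2, W3;
  arma::rowvec b1, b2, b3;
};

inline arma::mat lrelu(const arma::mat& z, const double slope) {
  return arma::max(z, slope * z);
}

inline arma::mat lrelu_grad(const arma::mat& z, const double slope) {
  arma::mat g(z.n_rows, z.n_cols);
  for (arma::uword i = 0; i < z.n_elem; ++i) g(i) = z(i) > 0.0 ? 1.0 : slope;
  return g;
}

// Forward pass caching pre-activations for backprop.
struct Cache {
  arma::mat Z1, A1, Z2, A2, R;
};

void forward(const Net& net, const arma::mat& X, const double slope, Cache& c) {
  c.Z1 = X * net.W1;
  c.Z1.each_row() += net.b1;
  c.A1 = lrelu(c.Z1, slope);
  c.Z2 = c.A1 * net.W2;
  c.Z2.each_row() += net.b2;
  c.A2 = lrelu(c.Z2, slope);
  arma::mat Z3 = c.A2 * net.W3;
  Z3.each_row() += net.b3;
  c.R = 1.0 / (1.0 + arma::exp(-Z3));
}

// Per-cell loss 1 - max_l cos(v, d_l) and, optionally, dL/dvu, dL/dvs for the
// argmax neighbor (hard-max subgradient). Zero-length vectors give cosine 0.
// `orient` (may be null) restricts the candidate neighbors of cell i to those
// whose spliced displacement agrees in sign with orient[i] (steady-state
// orientation phase of training); orient[i] == 0 leaves cell i unrestricted.
void cos_loss(const arma::vec& vu, const arma::vec& vs,
              const arma::mat& dU, const arma::mat& dS, const arma::mat& nd,
              const arma::uvec& rows, arma::vec& loss,
              arma::vec* gvu, arma::vec* gvs, const arma::ivec* orient) {
  const double eps = 1e-12;
  const arma::uword m = rows.n_elem;
  for (arma::uword ii = 0; ii < m; ++ii) {
    const arma::uword i = rows(ii);
    const int oi = (orient == nullptr) ? 0 : (*orient)(i);
    const double nv = std::sqrt(vu(ii) * vu(ii) + vs(ii) * vs(ii));
    double best = 0.0;
    int bl = -1;
    if (nv > eps) {
      for (arma::uword l = 0; l < dU.n_cols; ++l) {
        if (nd(i, l) <= eps) continue;
        if (oi != 0 && (oi * dS(i, l) < 0.0 || oi * dU(i, l) < 0.0)) continue;
        const double c = (vu(ii) * dU(i, l) + vs(ii) * dS(i, l)) / (nv * nd(i, l));
        if (bl < 0 || c > best) { best = c; bl = (int)l; }
      }
      if (bl < 0) best = 0.0;
    }
    loss(ii) = 1.0 - best;
    if (gvu != nullptr) {
      double gu = 0.0, gs = 0.0;
      if (bl >= 0 && nv > eps) {
        const double ndl = nd(i, (arma::uword)bl);
        // d cos / d v = d/(|v||d|) - cos * v/|v|^2 ; loss = 1 - cos
        gu = -(dU(i, (arma::uword)bl) / (nv * ndl) - best * vu(ii) / (nv * nv));
        gs = -(dS(i, (arma::uword)bl) / (nv * ndl) - best * vs(ii) / (nv * nv));
      }
      (*gvu)(ii) = gu;
      (*gvs)(ii) = gs;
    }
  }
}

arma::mat runif_mat(const int nr, const int nc, const double bound) {
  NumericVector v = Rcpp::runif(nr * nc, -bound, bound);
  return arma::mat(v.begin(), nr, nc);  // column-major fill
}

struct Adam {
  arma::mat mW1, vW1, mW2, vW2, mW3, vW3;
  arma::rowvec mb1, vb1, mb2, vb2, mb3, vb3;
  int t = 0;
  explicit Adam(const Net& n) {
    mW1.zeros(arma::size(n.W1)); vW1.zeros(arma::size(n.W1));
    mW2.zeros(arma::size(n.W2)); vW2.zeros(arma::size(n.W2));
    mW3.zeros(arma::size(n.W3)); vW3.zeros(arma::size(n.W3));
    mb1.zeros(arma::size(n.b1)); vb1.zeros(arma::size(n.b1));
    mb2.zeros(arma::size(n.b2)); vb2.zeros(arma::size(n.b2));
    mb3.zeros(arma::size(n.b3)); vb3.zeros(arma::size(n.b3));
  }
  template <typename M>
  void step_one(M& w, const M& g, M& mm, M& vv, const double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    w -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }
};

}  // namespace

// Train one gene's network. u, s are the max-scaled abundances; nbr is the
// n x k neighbor index matrix (1-based, self excluded). Returns rates,
// velocities (in scaled units), the checkpoint loss history and diagnostics.
// [[Rcpp::export]]
List train_gene_cpp(const arma::vec& u, const arma::vec& s,
                    const arma::imat& nbr, const double dt,
                    const double lr, const double weight_decay,
                    const int hidden, const double leaky_slope,
                    const double perm_ratio, const int check_every,
                    const int patience, const int max_epochs,
                    const bool early_stop, const arma::ivec& orient,
                    const int orient_epochs) {
  const int n = u.n_elem;
  const int k = nbr.n_cols;

  // Neighbor displacement field (the "observed velocity" candidates).
  arma::mat dU(n, k), dS(n, k), nd(n, k);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < k; ++l) {
      const int j = nbr(i, l) - 1;
      dU(i, l) = u(j) - u(i);
      dS(i, l) = s(j) - s(i);
      nd(i, l) = std::sqrt(dU(i, l) * dU(i, l) + dS(i, l) * dS(i, l));
    }
  }

  Net net;
  const double bnd1 = 1.0 / std::sqrt(2.0);
  const double bnd2 = 1.0 / std::sqrt((double)hidden);
  net.W1 = runif_mat(2, hidden, bnd1);
  net.b1 = runif_mat(1, hidden, bnd1).row(0);
  net.W2 = runif_mat(hidden, hidden, bnd2);
  net.b2 = runif_mat(1, hidden, bnd2).row(0);
  net.W3 = runif_mat(hidden, 3, bnd2);
  net.b3 = runif_mat(1, 3, bnd2).row(0);
  Adam opt(net);

  const arma::mat Xall = arma::join_rows(u, s);
  const int m = std::max(1, (int)std::lround(perm_ratio * n));

  // Checkpoint loss under the current training objective (masked while the
  // orientation constraint is active); the final reported loss is unmasked.
  auto full_loss = [&](Cache& c, const arma::ivec* msk) {
    forward(net, Xall, leaky_slope, c);
    arma::vec vu = dt * (c.R.col(0) - c.R.col(1) % u);
    arma::vec vs = dt * (c.R.col(1) % u - c.R.col(2) % s);
    arma::vec loss(n);
    arma::uvec rows = arma::regspace<arma::uvec>(0, n - 1);
    cos_loss(vu, vs, dU, dS, nd, rows, loss, nullptr, nullptr, msk);
    return arma::mean(loss);
  };

  std::vector<double> hist_epoch, hist_loss, hist_relay;
  Net best = net;
  double best_loss = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0, stopped_epoch = max_epochs;
  bool diverged = false;

  // Epoch 0 checkpoint: the untrained network's loss.
  {
    Cache c;
    const double l0 = full_loss(c, orient_epochs > 0 ? &orient : nullptr);
    hist_epoch.push_back(0.0);
    hist_loss.push_back(l0);
    hist_relay.push_back(orient_epochs > 0 ? full_loss(c, nullptr) : l0);
    if (std::isfinite(l0)) { best_loss = l0; best = net; best_epoch = 0; }
  }

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    IntegerVector pick = Rcpp::sample(n, m, false);
    arma::uvec rows(m);
    for (int i = 0; i < m; ++i) rows(i) = pick[i] - 1;

    const arma::mat Xb = Xall.rows(rows);
    const arma::vec ub = u.elem(rows), sb = s.elem(rows);
    Cache c;
    forward(net, Xb, leaky_slope, c);
    arma::vec a = c.R.col(0), b = c.R.col(1), g = c.R.col(2);
    arma::vec vu = dt * (a - b % ub);
    arma::vec vs = dt * (b % ub - g % sb);
    arma::vec loss(m), gvu(m), gvs(m);
    const arma::ivec* msk = (epoch <= orient_epochs) ? &orient : nullptr;
    cos_loss(vu, vs, dU, dS, nd, rows, loss, &gvu, &gvs, msk);

    // The summed loss over the sampled cells drives the gradient step (the
    // objective is a sum of per-cell losses, so step size scales with the
    // sampled-subset size).
    arma::mat dR(m, 3);
    dR.col(0) = dt * gvu;
    dR.col(1) = dt * (gvs - gvu) % ub;
    dR.col(2) = -dt * gvs % sb;
    arma::mat dZ3 = dR % (c.R % (1.0 - c.R));
    arma::mat gW3 = c.A2.t() * dZ3 + weight_decay * net.W3;
    arma::rowvec gb3 = arma::sum(dZ3, 0) + weight_decay * net.b3;
    arma::mat dA2 = dZ3 * net.W3.t();
    arma::mat dZ2 = dA2 % lrelu_grad(c.Z2, leaky_slope);
    arma::mat gW2 = c.A1.t() * dZ2 + weight_decay * net.W2;
    arma::rowvec gb2 = arma::sum(dZ2, 0) + weight_decay * net.b2;
    arma::mat dA1 = dZ2 * net.W2.t();
    arma::mat dZ1 = dA1 % lrelu_grad(c.Z1, leaky_slope);
    arma::mat gW1 = Xb.t() * dZ1 + weight_decay * net.W1;
    arma::rowvec gb1 = arma::sum(dZ1, 0) + weight_decay * net.b1;

    opt.t += 1;
    opt.step_one(net.W1, gW1, opt.mW1, opt.vW1, lr);
    opt.step_one(net.b1, gb1, opt.mb1, opt.vb1, lr);
    opt.step_one(net.W2, gW2, opt.mW2, opt.vW2, lr);
    opt.step_one(net.b2, gb2, opt.mb2, opt.vb2, lr);
    opt.step_one(net.W3, gW3, opt.mW3, opt.vW3, lr);
    opt.step_one(net.b3, gb3, opt.mb3, opt.vb3, lr);

    if (epoch % check_every == 0 || epoch == max_epochs) {
      Cache cf;
      const bool masked = epoch <= orient_epochs;
      const double l = full_loss(cf, masked ? &orient : nullptr);
      hist_epoch.push_back((double)epoch);
      hist_loss.push_back(l);
      hist_relay.push_back(masked ? full_loss(cf, nullptr) : l);
      if (!std::isfinite(l)) { diverged = true; stopped_epoch = epoch; break; }
      if (l < best_loss) {
        best_loss = l;
        best = net;
        best_epoch = epoch;
        bad = 0;
      } else {
        bad += 1;
        if (early_stop && bad >= patience) { stopped_epoch = epoch; break; }
      }
      if (epoch == max_epochs) stopped_epoch = epoch;
    }
  }

  // Evaluate everything at the best checkpoint.
  net = best;
  Cache cf;
  forward(net, Xall, leaky_slope, cf);
  arma::vec a = cf.R.col(0), b = cf.R.col(1), g = cf.R.col(2);
  arma::vec vu = dt * (a - b % u);
  arma::vec vs = dt * (b % u - g % s);
  arma::vec per_cell(n);
  arma::uvec rows = arma::regspace<arma::uvec>(0, n - 1);
  cos_loss(vu, vs, dU, dS, nd, rows, per_cell, nullptr, nullptr, nullptr);

  return List::create(
      _["alpha"] = a, _["beta"] = b, _["gamma"] = g,
      _["vu"] = vu, _["vs"] = vs,
      _["loss"] = arma::mean(per_cell), _["per_cell_loss"] = per_cell,
      _["epochs"] = hist_epoch, _["losses"] = hist_loss,
      _["relay_losses"] = hist_relay,
      _["best_checkpoint_loss"] = best_loss,
      _["best_epoch"] = best_epoch, _["stopped_epoch"] = stopped_epoch,
      _["diverged"] = diverged,
      _["net"] = List::create(_["W1"] = net.W1, _["b1"] = net.b1,
                              _["W2"] = net.W2, _["b2"] = net.b2,
                              _["W3"] = net.W3, _["b3"] = net.b3,
                              _["leaky_slope"] = leaky_slope));
}

// Apply a trained network to (scaled) abundances; returns an n x 3 matrix of
// rates (alpha, beta, gamma).
// [[Rcpp::export]]
arma::mat mlp_rates_cpp(const List& netlist, const arma::vec& u,
                        const arma::vec& s) {
  Net net;
  net.W1 = as<arma::mat>(netlist["W1"]);
  net.b1 = as<arma::rowvec>(netlist["b1"]);
  net.W2 = as<arma::mat>(netlist["W2"]);
  net.b2 = as<arma::rowvec>(netlist["b2"]);
  net.W3 = as<arma::mat>(netlist["W3"]);
  net.b3 = as<arma::rowvec>(netlist["b3"]);
  const double slope = as<double>(netlist["leaky_slope"]);
  Cache c;
  forward(net, arma::join_rows(u, s), slope, c);
  return c.R;
}
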