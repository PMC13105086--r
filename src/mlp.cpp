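// Multilayer perceptron for tabular regression / binary-probability tasks.
// Fully connected ReLU network trained with Adam on a (optionally weighted)
// mini-batch loss, early stopping on a held-out validation split.
// Inputs are expected pre-standardized by the R wrapper.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

// forward pass on column-major batch A0 (p x m); caches activations
// task 0 = regression (linear output), 1 = binary (logit output)
arma::rowvec forward(const Net &net, const arma::mat &A0,
                     std::vector<arma::mat> *cache) {
  arma::mat A = A0;
  size_t L = net.W.size();
  if (cache) cache->clear();
  for (size_t l = 0; l + 1 < L; ++l) {
    A = net.W[l] * A;
    A.each_col() += net.b[l];
    A.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
    if (cache) cache->push_back(A);
  }
  arma::mat out = net.W[L - 1] * A;
  out.each_col() += net.b[L - 1];
  return arma::rowvec(out.row(0));
}

double loss_value(const arma::rowvec &z, const arma::rowvec &y,
                  const arma::rowvec &w, int task) {
  arma::rowvec per(z.n_elem);
  if (task == 0) {
    per = arma::square(z - y);
  } else {
    // numerically stable BCE with logits: max(z,0) - z*y + log1p(exp(-|z|))
    for (arma::uword i = 0; i < z.n_elem; ++i) {
      double zi = z[i];
      per[i] = std::max(zi, 0.0) - zi * y[i] + std::log1p(std::exp(-std::fabs(zi)));
    }
  }
  return arma::dot(per, w) / arma::accu(w);
}

}  // namespace

// [[Rcpp::export(name = ".mlp_fit_cpp")]]
List mlp_fit_cpp(const arma::mat &X, const arma::vec &y, const arma::vec &w,
                 const arma::ivec &hidden, int task, int epochs, int batch,
                 double lr, double val_frac, int patience, int seed) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(static_cast<uint32_t>(seed));

  // layer sizes
  std::vector<arma::uword> sz;
  sz.push_back(p);
  for (arma::uword l = 0; l < hidden.n_elem; ++l)
    sz.push_back(static_cast<arma::uword>(hidden[l]));
  sz.push_back(1);
  const size_t L = sz.size() - 1;

  // He-normal init
  Net net;
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (size_t l = 0; l < L; ++l) {
    arma::mat Wl(sz[l + 1], sz[l]);
    double s = std::sqrt(2.0 / static_cast<double>(sz[l]));
    for (arma::uword i = 0; i < Wl.n_elem; ++i) Wl[i] = s * gauss(rng);
    net.W.push_back(Wl);
    net.b.push_back(arma::vec(sz[l + 1], arma::fill::zeros));
  }

  // train / validation split
  std::vector<arma::uword> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::shuffle(idx.begin(), idx.end(), rng);
  arma::uword n_val = static_cast<arma::uword>(std::floor(val_frac * n));
  if (val_frac > 0 && n_val < 1 && n >= 10) n_val = 1;
  arma::uword n_tr = n - n_val;
  arma::uvec tr(n_tr), va(n_val);
  for (arma::uword i = 0; i < n_tr; ++i) tr[i] = idx[i];
  for (arma::uword i = 0; i < n_val; ++i) va[i] = idx[n_tr + i];

  arma::mat Xtr = X.rows(tr).t();  // p x n_tr, column-major batches
  arma::rowvec ytr = y.elem(tr).t(), wtr = w.elem(tr).t();
  arma::mat Xva;
  arma::rowvec yva, wva;
  if (n_val > 0) {
    Xva = X.rows(va).t();
    yva = y.elem(va).t();
    wva = w.elem(va).t();
  }

  // Adam state
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(net.W[l]));
    vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(arma::size(net.b[l]));
    vb[l].zeros(arma::size(net.b[l]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t_step = 0;

  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int bad_epochs = 0, epochs_run = 0;

  std::vector<arma::uword> order(n_tr);
  std::iota(order.begin(), order.end(), 0);
  std::vector<arma::mat> acts;

  for (int ep = 0; ep < epochs; ++ep) {
    epochs_run = ep + 1;
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n_tr; start += batch) {
      arma::uword stop = std::min<arma::uword>(start + batch, n_tr);
      arma::uword m = stop - start;
      arma::uvec bidx(m);
      for (arma::uword i = 0; i < m; ++i) bidx[i] = order[start + i];

      arma::mat A0 = Xtr.cols(bidx);
      arma::rowvec yb = ytr.elem(bidx).t(), wb = wtr.elem(bidx).t();

      arma::rowvec z = forward(net, A0, &acts);

      // output-layer delta (d loss / d z), weighted, mean over batch
      double wsum = arma::accu(wb);
      arma::rowvec delta;
      if (task == 0) {
        delta = 2.0 * (z - yb) % wb / wsum;
      } else {
        arma::rowvec pr = 1.0 / (1.0 + arma::exp(-z));
        delta = (pr - yb) % wb / wsum;
      }

      // backprop
      std::vector<arma::mat> gW(L);
      std::vector<arma::vec> gb(L);
      arma::mat D = arma::mat(delta);  // 1 x m
      for (size_t l = L; l-- > 0;) {
        const arma::mat &Aprev = (l == 0) ? A0 : acts[l - 1];
        gW[l] = D * Aprev.t();
        gb[l] = arma::sum(D, 1);
        if (l > 0) {
          D = net.W[l].t() * D;
          D %= arma::conv_to<arma::mat>::from(acts[l - 1] > 0.0);  // ReLU'
        }
      }

      // Adam update
      ++t_step;
      double c1 = 1.0 - std::pow(b1, (double)t_step);
      double c2 = 1.0 - std::pow(b2, (double)t_step);
      for (size_t l = 0; l < L; ++l) {
        mW[l] = b1 * mW[l] + (1 - b1) * gW[l];
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW[l]);
        net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = b1 * mb[l] + (1 - b1) * gb[l];
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb[l]);
        net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }

    if (n_val > 0) {
      arma::rowvec zv = forward(net, Xva, nullptr);
      double vloss = loss_value(zv, yva, wva, task);
      if (vloss < best_val - 1e-12) {
        best_val = vloss;
        best = net;
        bad_epochs = 0;
      } else if (++bad_epochs >= patience) {
        break;
      }
    }
  }
  if (n_val == 0) {
    best = net;
    arma::rowvec zt = forward(net, Xtr, nullptr);
    best_val = loss_value(zt, ytr, wtr, task);
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = best.W[l];
    bout[l] = best.b[l];
  }
  return List::create(_["W"] = Wout, _["b"] = bout, _["task"] = task,
                      _["val_loss"] = best_val, _["epochs_run"] = epochs_run);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(const List &model, const arma::mat &X) {
  Net net;
  List Wl = model["W"], bl = model["b"];
  for (R_xlen_t l = 0; l < Wl.size(); ++l) {
    net.W.push_back(as<arma::mat>(Wl[l]));
    net.b.push_back(as<arma::vec>(bl[l]));
  }
  arma::rowvec z = forward(net, X.t(), nullptr);
  int task = as<int>(model["task"]);
  arma::vec out = z.t();
  if (task == 1) out = 1.0 / (1.0 + arma::exp(-out));
  return out;
}
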