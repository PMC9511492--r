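// Dense feed-forward network with tanh hidden activations and a linear
// output layer, trained by minibatch Adam on mean-squared error.
// Kept deliberately small: fixed MLP topology, no regularisation beyond
// early data splitting, deterministic given the seed. Computation runs in
// single precision (the regression targets are O(1) and the parameter
// deltas of interest are far above float resolution); the R boundary is
// double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::fmat> W;
  std::vector<arma::frowvec> b;
};

// forward pass; caches layer activations for backprop
void forward(const Net& net, const arma::fmat& X, std::vector<arma::fmat>& A) {
  const size_t L = net.W.size();
  A.resize(L + 1);
  A[0] = X;
  for (size_t l = 0; l < L; ++l) {
    arma::fmat Z = A[l] * net.W[l];
    Z.each_row() += net.b[l];
    A[l + 1] = (l + 1 < L) ? arma::fmat(arma::tanh(Z)) : Z;
  }
}

double mse_loss(const Net& net, const arma::fmat& X, const arma::fmat& Y) {
  std::vector<arma::fmat> A;
  forward(net, X, A);
  const arma::fmat D = A.back() - Y;
  return arma::accu(arma::square(D)) / double(D.n_elem);
}

}  // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                   const IntegerVector& hidden,
                   int epochs, int batch_size, double val_frac,
                   double lr, double lr_decay, int seed, int verbose_every) {
  if (X.n_rows != Y.n_rows) stop("X and Y must have the same number of rows");
  const arma::uword n = X.n_rows;
  std::mt19937 rng(static_cast<unsigned int>(seed));

  // layer widths: d_in, hidden..., d_out
  std::vector<arma::uword> width;
  width.push_back(X.n_cols);
  for (int h : hidden) width.push_back(static_cast<arma::uword>(h));
  width.push_back(Y.n_cols);
  const size_t L = width.size() - 1;

  // Glorot-uniform initialisation, seeded
  Net net;
  net.W.resize(L);
  net.b.resize(L);
  for (size_t l = 0; l < L; ++l) {
    const double lim = std::sqrt(6.0 / double(width[l] + width[l + 1]));
    std::uniform_real_distribution<double> unif(-lim, lim);
    net.W[l].set_size(width[l], width[l + 1]);
    for (arma::uword j = 0; j < net.W[l].n_elem; ++j) {
      net.W[l](j) = static_cast<float>(unif(rng));
    }
    net.b[l] = arma::frowvec(width[l + 1], arma::fill::zeros);
  }

  // shuffled split: validation = trailing fraction of the shuffled set
  arma::uvec perm(n);
  std::iota(perm.begin(), perm.end(), 0);
  std::shuffle(perm.begin(), perm.end(), rng);
  const arma::uword n_val = static_cast<arma::uword>(std::floor(val_frac * n));
  const arma::uword n_tr = n - n_val;
  if (n_tr < 1) stop("validation fraction leaves no training data");
  const arma::fmat Xtr = arma::conv_to<arma::fmat>::from(X.rows(perm.head(n_tr)));
  const arma::fmat Ytr = arma::conv_to<arma::fmat>::from(Y.rows(perm.head(n_tr)));
  arma::fmat Xva, Yva;
  if (n_val) {
    Xva = arma::conv_to<arma::fmat>::from(X.rows(perm.tail(n_val)));
    Yva = arma::conv_to<arma::fmat>::from(Y.rows(perm.tail(n_val)));
  }

  // Adam state
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  std::vector<arma::fmat> mW(L), vW(L);
  std::vector<arma::frowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(net.W[l])); vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(net.b[l].n_elem);      vb[l].zeros(net.b[l].n_elem);
  }

  arma::vec train_hist(epochs), val_hist(epochs);
  std::vector<arma::fmat> A;
  std::vector<arma::fmat> dW(L);
  std::vector<arma::frowvec> db(L);
  arma::uvec order(n_tr);
  std::iota(order.begin(), order.end(), 0);
  long long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    const float lr_ep = static_cast<float>(lr * std::pow(lr_decay, ep));
    double run_loss = 0.0;
    arma::uword n_seen = 0;

    for (arma::uword start = 0; start < n_tr; start += batch_size) {
      const arma::uword stop_ = std::min<arma::uword>(start + batch_size, n_tr) - 1;
      const arma::uvec idx = order.subvec(start, stop_);
      const arma::fmat Xb = Xtr.rows(idx);
      const arma::fmat Yb = Ytr.rows(idx);
      const arma::uword m = Xb.n_rows;

      forward(net, Xb, A);
      arma::fmat delta = (A[L] - Yb) * (2.0f / float(Yb.n_elem));
      run_loss += arma::accu(arma::square(A[L] - Yb)) / double(Yb.n_cols);
      n_seen += m;

      for (size_t l = L; l-- > 0;) {
        dW[l] = A[l].t() * delta;
        db[l] = arma::sum(delta, 0);
        if (l > 0) delta = (delta * net.W[l].t()) % (1.0f - arma::square(A[l]));
      }

      ++step;
      const float c1 = 1.0f - std::pow(b1, float(step));
      const float c2 = 1.0f - std::pow(b2, float(step));
      for (size_t l = 0; l < L; ++l) {
        mW[l] = b1 * mW[l] + (1.0f - b1) * dW[l];
        vW[l] = b2 * vW[l] + (1.0f - b2) * arma::square(dW[l]);
        net.W[l] -= lr_ep * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = b1 * mb[l] + (1.0f - b1) * db[l];
        vb[l] = b2 * vb[l] + (1.0f - b2) * arma::square(db[l]);
        net.b[l] -= lr_ep * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }

    train_hist(ep) = run_loss / double(n_seen);
    val_hist(ep) = n_val ? mse_loss(net, Xva, Yva) : NA_REAL;
    if (!std::isfinite(train_hist(ep)))
      stop("training diverged at epoch %d (non-finite loss)", ep + 1);
    if (verbose_every > 0 && ((ep + 1) % verbose_every == 0 || ep == 0))
      Rcout << "epoch " << ep + 1 << "/" << epochs
            << "  train " << train_hist(ep)
            << "  val " << val_hist(ep) << "\n";
    Rcpp::checkUserInterrupt();
  }

  List W(L), B(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = wrap(arma::conv_to<arma::mat>::from(net.W[l]));
    B[l] = wrap(arma::conv_to<arma::vec>::from(net.b[l].t()));
  }
  return List::create(_["weights"] = W, _["biases"] = B,
                      _["train_loss"] = train_hist, _["val_loss"] = val_hist,
                      _["n_train"] = (double)n_tr, _["n_val"] = (double)n_val);
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(const List& weights, const List& biases,
                          const arma::mat& X) {
  const size_t L = weights.size();
  Net net;
  net.W.resize(L);
  net.b.resize(L);
  for (size_t l = 0; l < L; ++l) {
    net.W[l] = arma::conv_to<arma::fmat>::from(as<arma::mat>(weights[l]));
    arma::fvec bv = arma::conv_to<arma::fvec>::from(as<arma::vec>(biases[l]));
    net.b[l] = bv.t();
  }
  if (X.n_cols != net.W[0].n_rows) stop("input width does not match the model");
  std::vector<arma::fmat> A;
  forward(net, arma::conv_to<arma::fmat>::from(X), A);
  return arma::conv_to<arma::mat>::from(A.back());
}
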