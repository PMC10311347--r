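// Mini-batch Adam training for the two-hidden-layer classifier.
// The epoch shuffles are drawn in R (seeded) and passed in, so results
// are fully reproducible and the R level owns all randomness.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Adam {
  arma::mat m, v;
  explicit Adam(const arma::mat& w) : m(arma::size(w), arma::fill::zeros),
                                      v(arma::size(w), arma::fill::zeros) {}
  // Single fused pass over the arrays; the update is memory-bound, so
  // avoiding expression-template temporaries matters here.
  void step(arma::mat& w, const arma::mat& g, int t, double lr,
            double b1, double b2, double eps) {
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    double* wp = w.memptr();
    double* mp = m.memptr();
    double* vp = v.memptr();
    const double* gp = g.memptr();
    const arma::uword nn = w.n_elem;
    for (arma::uword i = 0; i < nn; ++i) {
      mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
      vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
      wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
    }
  }
};

// Per-row stable softmax cross-entropy on 2-class logits; fills dZ with
// (p - onehot) / batch_n and returns the summed loss.
double softmax_ce_grad(const arma::mat& z, const arma::ivec& y,
                       arma::mat& dz) {
  const arma::uword n = z.n_rows;
  double loss = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double z0 = z(i, 0), z1 = z(i, 1);
    const double m = std::max(z0, z1);
    const double lse = m + std::log(std::exp(z0 - m) + std::exp(z1 - m));
    loss += lse - (y[i] == 1 ? z1 : z0);
    const double p0 = std::exp(z0 - lse), p1 = std::exp(z1 - lse);
    dz(i, 0) = (p0 - (y[i] == 0 ? 1.0 : 0.0)) / n;
    dz(i, 1) = (p1 - (y[i] == 1 ? 1.0 : 0.0)) / n;
  }
  return loss;
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_fnn(const arma::mat& X, const arma::ivec& y,
                   arma::mat W1, arma::rowvec b1,
                   arma::mat W2, arma::rowvec b2,
                   arma::mat W3, arma::rowvec b3,
                   const arma::imat& perms, int batch_size,
                   double lr, double beta1, double beta2, double eps,
                   const LogicalVector& freeze) {
  const int epochs = perms.n_rows;
  const arma::uword n = X.n_rows;
  const bool f1 = freeze[0], f2 = freeze[1], f3 = freeze[2];

  Adam aW1(W1), ab1(b1), aW2(W2), ab2(b2), aW3(W3), ab3(b3);
  arma::vec losses(epochs, arma::fill::zeros);
  int t = 0;

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      const arma::uword stop = std::min(
          n, start + static_cast<arma::uword>(batch_size));
      arma::uvec idx(stop - start);
      for (arma::uword k = start; k < stop; ++k) {
        idx[k - start] = static_cast<arma::uword>(perms(e, k) - 1);
      }
      const arma::mat Xb = X.rows(idx);
      arma::ivec yb(idx.n_elem);
      for (arma::uword k = 0; k < idx.n_elem; ++k) yb[k] = y[idx[k]];

      arma::mat H1 = Xb * W1;
      H1.each_row() += b1;
      H1.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat H2 = H1 * W2;
      H2.each_row() += b2;
      H2.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat Z = H2 * W3;
      Z.each_row() += b3;

      arma::mat dZ(arma::size(Z));
      epoch_loss += softmax_ce_grad(Z, yb, dZ);
      ++t;

      arma::mat gW3, dH2, gW2, dH1, gW1;
      arma::rowvec gb3, gb2, gb1;
      if (!f3) { gW3 = H2.t() * dZ; gb3 = arma::sum(dZ, 0); }
      if (!f1 || !f2) {
        dH2 = (dZ * W3.t()) % (H2 > 0);
        if (!f2) { gW2 = H1.t() * dH2; gb2 = arma::sum(dH2, 0); }
        if (!f1) {
          dH1 = (dH2 * W2.t()) % (H1 > 0);
          gW1 = Xb.t() * dH1; gb1 = arma::sum(dH1, 0);
        }
      }
      if (!f3) { aW3.step(W3, gW3, t, lr, beta1, beta2, eps);
                 ab3.step(b3, gb3, t, lr, beta1, beta2, eps); }
      if (!f2) { aW2.step(W2, gW2, t, lr, beta1, beta2, eps);
                 ab2.step(b2, gb2, t, lr, beta1, beta2, eps); }
      if (!f1) { aW1.step(W1, gW1, t, lr, beta1, beta2, eps);
                 ab1.step(b1, gb1, t, lr, beta1, beta2, eps); }
    }
    losses[e] = epoch_loss / static_cast<double>(n);
    if (e % 32 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2,
                      _["b2"] = b2, _["W3"] = W3, _["b3"] = b3,
                      _["losses"] = losses);
}

// Output-layer-only training on a fixed (frozen) hidden representation.
// [[Rcpp::export]]
List cpp_train_softmax(const arma::mat& H, const arma::ivec& y,
                       arma::mat W3, arma::rowvec b3,
                       const arma::imat& perms, int batch_size,
                       double lr, double beta1, double beta2, double eps) {
  const int epochs = perms.n_rows;
  const arma::uword n = H.n_rows;
  Adam aW3(W3), ab3(b3);
  arma::vec losses(epochs, arma::fill::zeros);
  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      const arma::uword stop = std::min(
          n, start + static_cast<arma::uword>(batch_size));
      arma::uvec idx(stop - start);
      for (arma::uword k = start; k < stop; ++k) {
        idx[k - start] = static_cast<arma::uword>(perms(e, k) - 1);
      }
      const arma::mat Hb = H.rows(idx);
      arma::ivec yb(idx.n_elem);
      for (arma::uword k = 0; k < idx.n_elem; ++k) yb[k] = y[idx[k]];
      arma::mat Z = Hb * W3;
      Z.each_row() += b3;
      arma::mat dZ(arma::size(Z));
      epoch_loss += softmax_ce_grad(Z, yb, dZ);
      ++t;
      arma::mat gW3 = Hb.t() * dZ;
      arma::rowvec gb3 = arma::sum(dZ, 0);
      aW3.step(W3, gW3, t, lr, beta1, beta2, eps);
      ab3.step(b3, gb3, t, lr, beta1, beta2, eps);
    }
    losses[e] = epoch_loss / static_cast<double>(n);
    if (e % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["W3"] = W3, _["b3"] = b3, _["losses"] = losses);
}
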