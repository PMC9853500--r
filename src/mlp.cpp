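#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Single-hidden-layer perceptron with logistic activations on both
// layers, trained by full-batch gradient descent with classical momentum
// on the (optionally per-sample weighted) sum-of-squares loss
// E = 0.5 * sum(w_i * (a_i - t_i)^2). The learning rate applies to the
// per-sample mean gradient so it is insensitive to n.

static arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

static void forward(const arma::mat& X, const arma::mat& W1,
                    const arma::rowvec& b1, const arma::mat& W2,
                    const arma::rowvec& b2, arma::mat& H, arma::mat& A) {
  H = sigm(X * W1 + arma::repmat(b1, X.n_rows, 1));
  A = sigm(H * W2 + arma::repmat(b2, H.n_rows, 1));
}

// [[Rcpp::export]]
List mlp_forward_cpp(const arma::mat& X, const arma::mat& W1,
                     const arma::rowvec& b1, const arma::mat& W2,
                     const arma::rowvec& b2) {
  arma::mat H, A;
  forward(X, W1, b1, W2, b2, H, A);
  return List::create(_["hidden"] = H, _["output"] = A);
}

// [[Rcpp::export]]
double mlp_loss_cpp(const arma::mat& X, const arma::mat& T,
                    const arma::mat& W1, const arma::rowvec& b1,
                    const arma::mat& W2, const arma::rowvec& b2) {
  arma::mat H, A;
  forward(X, W1, b1, W2, b2, H, A);
  return 0.5 * arma::accu(arma::square(A - T));
}

// [[Rcpp::export]]
List mlp_grad_cpp(const arma::mat& X, const arma::mat& T,
                  const arma::mat& W1, const arma::rowvec& b1,
                  const arma::mat& W2, const arma::rowvec& b2) {
  arma::mat H, A;
  forward(X, W1, b1, W2, b2, H, A);
  arma::mat dA = (A - T) % A % (1.0 - A);
  arma::mat gW2 = H.t() * dA;
  arma::rowvec gb2 = arma::sum(dA, 0);
  arma::mat dH = (dA * W2.t()) % H % (1.0 - H);
  arma::mat gW1 = X.t() * dH;
  arma::rowvec gb1 = arma::sum(dH, 0);
  return List::create(_["W1"] = gW1, _["b1"] = gb1,
                      _["W2"] = gW2, _["b2"] = gb2);
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& T,
                   const arma::vec& w,
                   arma::mat W1, arma::rowvec b1,
                   arma::mat W2, arma::rowvec b2,
                   const int max_epochs, const double learning_rate,
                   const double momentum, const double tol,
                   const int patience, const double rmse_target) {
  const double n = static_cast<double>(X.n_rows);
  const double scale = learning_rate / n;
  arma::mat vW1(arma::size(W1), arma::fill::zeros);
  arma::rowvec vb1(arma::size(b1), arma::fill::zeros);
  arma::mat vW2(arma::size(W2), arma::fill::zeros);
  arma::rowvec vb2(arma::size(b2), arma::fill::zeros);
  arma::vec history(max_epochs, arma::fill::none);
  double prev_rmse = arma::datum::inf;
  int stalled = 0, epoch = 0;
  bool diverged = false;
  arma::mat H, A;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    forward(X, W1, b1, W2, b2, H, A);
    arma::mat dA = (A - T) % A % (1.0 - A);
    dA.each_col() %= w;  // per-sample loss weights (class balancing)
    arma::mat dH = (dA * W2.t()) % H % (1.0 - H);

    vW2 = momentum * vW2 - scale * (H.t() * dA);
    vb2 = momentum * vb2 - scale * arma::sum(dA, 0);
    vW1 = momentum * vW1 - scale * (X.t() * dH);
    vb1 = momentum * vb1 - scale * arma::sum(dH, 0);
    W2 += vW2; b2 += vb2; W1 += vW1; b1 += vb1;

    arma::mat sq = arma::square(A - T);
    sq.each_col() %= w;
    double rmse = std::sqrt(arma::accu(sq) / (A.n_rows * A.n_cols));
    history(epoch) = rmse;
    if (!std::isfinite(rmse)) { diverged = true; ++epoch; break; }
    if (rmse <= rmse_target) { ++epoch; break; }
    if (std::abs(prev_rmse - rmse) < tol) {
      if (++stalled >= patience) { ++epoch; break; }
    } else {
      stalled = 0;
    }
    prev_rmse = rmse;
  }
  return List::create(
      _["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
      _["history"] = history.head(epoch), _["epochs"] = epoch,
      _["diverged"] = diverged);
}
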