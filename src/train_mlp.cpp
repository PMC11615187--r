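// Incremental (per-pattern) backpropagation with momentum and an adaptive
// learning rate for a single-hidden-layer tanh network with linear outputs.
// All randomness (initial weights, pattern order, splits) is supplied by the
// caller, so the routine itself is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double subset_mse(const mat& Xt, const mat& Yt,
                         const mat& W1, const vec& b1,
                         const mat& W2, const vec& b2) {
  // Xt: K x n, Yt: M x n (column-per-pattern layout)
  mat A1 = tanh(W1 * Xt + repmat(b1, 1, Xt.n_cols));
  mat E  = Yt - (W2 * A1 + repmat(b2, 1, Xt.n_cols));
  return accu(square(E)) / (E.n_rows * E.n_cols);
}

// [[Rcpp::export]]
Rcpp::List train_mlp_cpp(const arma::mat& X, const arma::mat& Y,
                         arma::mat W1, arma::vec b1,
                         arma::mat W2, arma::vec b2,
                         const arma::uvec& train_idx,
                         const arma::uvec& val_idx,
                         const arma::uvec& order,
                         double lr0, double momentum,
                         int max_epochs, int patience,
                         double lr_inc, double lr_dec,
                         double err_ratio) {
  const uword n_train = train_idx.n_elem;
  // column-major pattern layout for cheap column views
  mat Xtr = X.rows(train_idx).t();   // K x n_train
  mat Ytr = Y.rows(train_idx).t();   // M x n_train
  mat Xva, Yva;
  const bool has_val = val_idx.n_elem > 0;
  if (has_val) { Xva = X.rows(val_idx).t(); Yva = Y.rows(val_idx).t(); }

  mat vW1(size(W1), fill::zeros), vW2(size(W2), fill::zeros);
  vec vb1(size(b1), fill::zeros), vb2(size(b2), fill::zeros);

  double lr = lr0;
  double prev_mse = datum::inf;
  double best_val = datum::inf;
  mat bW1 = W1, bW2 = W2; vec bb1 = b1, bb2 = b2;
  int stall = 0, retries = 0, epochs_run = 0;
  std::vector<double> tr_trace, va_trace, lr_trace;

  int epoch = 0;
  while (epoch < max_epochs) {
    // snapshot for rejection / divergence recovery
    mat sW1 = W1, sW2 = W2; vec sb1 = b1, sb2 = b2;
    mat svW1 = vW1, svW2 = vW2; vec svb1 = vb1, svb2 = vb2;

    for (uword k = 0; k < n_train; ++k) {
      const uword i = order[k];
      vec x = Xtr.col(i);
      vec a1 = tanh(W1 * x + b1);
      vec e  = Ytr.col(i) - (W2 * a1 + b2);
      vec d1 = (W2.t() * e) % (1.0 - square(a1));
      vW2 = momentum * vW2 + lr * (e * a1.t());
      vb2 = momentum * vb2 + lr * e;
      vW1 = momentum * vW1 + lr * (d1 * x.t());
      vb1 = momentum * vb1 + lr * d1;
      W2 += vW2; b2 += vb2; W1 += vW1; b1 += vb1;
    }

    double mse = subset_mse(Xtr, Ytr, W1, b1, W2, b2);

    if (!std::isfinite(mse)) {
      // divergence: restore and retry this epoch with a halved rate
      W1 = sW1; W2 = sW2; b1 = sb1; b2 = sb2;
      vW1.zeros(); vW2.zeros(); vb1.zeros(); vb2.zeros();
      lr *= 0.5;
      if (++retries > 5)
        Rcpp::stop("training diverged (MSE not finite) after 5 learning-rate halvings");
      continue;
    }

    if (mse > err_ratio * prev_mse) {
      // adaptive-rate rule: reject the epoch's update, shrink the rate
      W1 = sW1; W2 = sW2; b1 = sb1; b2 = sb2;
      vW1 = svW1; vW2 = svW2; vb1 = svb1; vb2 = svb2;
      lr *= lr_dec;
      mse = prev_mse;
    } else if (mse < prev_mse) {
      lr *= lr_inc;
      prev_mse = mse;
    } else {
      // accepted but not improving: the incremental updates are at their
      // noise floor, so anneal the rate
      lr *= lr_dec;
    }

    double vmse = has_val ? subset_mse(Xva, Yva, W1, b1, W2, b2) : mse;
    tr_trace.push_back(mse); va_trace.push_back(vmse); lr_trace.push_back(lr);
    ++epoch; ++epochs_run;

    if (vmse < best_val - 1e-12) {
      best_val = vmse; bW1 = W1; bW2 = W2; bb1 = b1; bb2 = b2; stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
    Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("best_val_mse") = best_val,
    Rcpp::Named("epochs") = epochs_run,
    Rcpp::Named("train_mse_trace") = tr_trace,
    Rcpp::Named("val_mse_trace") = va_trace,
    Rcpp::Named("lr_trace") = lr_trace);
}
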