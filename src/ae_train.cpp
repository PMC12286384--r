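// Compiled core of the row-sparse autoencoder trainer.
// Mirrors the R-level objective/gradient definitions exactly; all random
// draws (weight init, validation split, batch order) come from R's RNG so
// results are reproducible under set.seed() and replicate protocols that
// advance one generator stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat glorot(int fan_in, int fan_out, bool nonneg = false) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  NumericVector u = runif(fan_in * fan_out, nonneg ? 0.0 : -lim, lim);
  // column-major fill matches matrix(runif(...), fan_in, fan_out) in R
  return arma::mat(u.begin(), fan_in, fan_out);
}

static double penalty_value(const arma::mat& w, bool l21) {
  if (l21) return arma::accu(arma::sqrt(arma::sum(arma::square(w), 1)));
  return arma::accu(arma::square(w));
}

static arma::mat penalty_grad(const arma::mat& w, bool l21) {
  if (!l21) return 2.0 * w;
  arma::vec rn = arma::sqrt(arma::sum(arma::square(w), 1));
  arma::mat g = w;
  for (arma::uword i = 0; i < w.n_rows; ++i) {
    g.row(i) = rn(i) > 0 ? w.row(i) / rn(i) : arma::rowvec(w.n_cols,
                                                           arma::fill::zeros);
  }
  return g;
}

struct Forward {
  arma::mat z1, a1, z2, xhat;
};

static Forward forward(const arma::mat& x, const arma::mat& w1,
                       const arma::mat& w2, const arma::rowvec& b1,
                       const arma::rowvec& b2, bool use_bias) {
  Forward f;
  f.z1 = x * w1;
  if (use_bias) f.z1.each_row() += b1;
  f.a1 = arma::clamp(f.z1, 0.0, arma::datum::inf);
  f.z2 = f.a1 * w2;
  if (use_bias) f.z2.each_row() += b2;
  f.xhat = arma::clamp(f.z2, 0.0, arma::datum::inf);
  return f;
}

static double objective(const arma::mat& x, const arma::mat& w1,
                        const arma::mat& w2, const arma::rowvec& b1,
                        const arma::rowvec& b2, bool use_bias,
                        double lambda, bool l21) {
  Forward f = forward(x, w1, w2, b1, b2, use_bias);
  double sse = arma::accu(arma::square(x - f.xhat));
  return sse / (2.0 * x.n_rows) + lambda * penalty_value(w1, l21);
}

class Adam {
public:
  arma::mat m, v;
  Adam(arma::uword r, arma::uword c)
    : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat& p, const arma::mat& g, double lr, double b1,
            double b2, double eps, long t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * arma::square(g);
    arma::mat mhat = m / (1.0 - std::pow(b1, (double)t));
    arma::mat vhat = v / (1.0 - std::pow(b2, (double)t));
    p -= lr * mhat / (arma::sqrt(vhat) + eps);
  }
};

// [[Rcpp::export(name = ".ae_train_cpp")]]
List ae_train_cpp(const arma::mat& x, int h, double lambda, int batch_size,
                  int epochs, double learning_rate, double beta1,
                  double beta2, double epsilon, double lr_decay,
                  double decay_start, double val_fraction, bool l21,
                  bool use_bias, bool nonneg_init, double b1_init,
                  double init_scale, double lambda_warmup) {
  const int n = x.n_rows, d = x.n_cols;

  // internal validation split, drawn like sample.int(n) in R
  IntegerVector idx = sample(n, n, false);  // 1-based permutation
  int n_val = (int)std::floor(val_fraction * n);
  arma::uvec val_idx(n_val), tr_idx(n - n_val);
  for (int i = 0; i < n_val; ++i) val_idx(i) = idx[i] - 1;
  for (int i = n_val; i < n; ++i) tr_idx(i - n_val) = idx[i] - 1;
  arma::mat xtr = x.rows(arma::sort(tr_idx));
  arma::mat xval = n_val > 0 ? x.rows(arma::sort(val_idx)) : arma::mat();

  arma::mat w1 = init_scale * glorot(d, h, nonneg_init);
  arma::mat w2 = init_scale * glorot(h, d, nonneg_init);
  arma::rowvec b1v(h), b2v(d, arma::fill::zeros);
  b1v.fill(use_bias ? b1_init : 0.0);

  Adam opt_w1(d, h), opt_w2(h, d), opt_b1(1, h), opt_b2(1, d);
  long t_step = 0;
  const int ntr = xtr.n_rows;
  NumericVector train_loss(epochs), val_loss(epochs);
  double best = R_PosInf;
  int best_epoch = NA_INTEGER;
  arma::mat best_w1 = w1, best_w2 = w2;
  arma::rowvec best_b1 = b1v, best_b2 = b2v;
  double lr = learning_rate;
  const int decay_from = (int)std::floor(decay_start * epochs);

  const int warm_epochs = (int)std::floor(lambda_warmup * epochs);
  for (int ep = 1; ep <= epochs; ++ep) {
    if (ep > decay_from) lr *= lr_decay;
    double lam_ep = warm_epochs > 0 && ep <= warm_epochs
      ? lambda * (double)ep / (double)warm_epochs : lambda;
    IntegerVector ord = sample(ntr, ntr, false);
    for (int s = 0; s < ntr; s += batch_size) {
      int e = std::min(s + batch_size, ntr);
      arma::uvec rows(e - s);
      for (int i = s; i < e; ++i) rows(i - s) = ord[i] - 1;
      arma::mat xb = xtr.rows(rows);

      Forward f = forward(xb, w1, w2, b1v, b2v, use_bias);
      arma::mat d_xhat = (f.xhat - xb) / (double)xb.n_rows;
      arma::mat d_z2 = d_xhat % (f.z2 > 0);
      arma::mat g_w2 = f.a1.t() * d_z2;
      arma::mat d_a1 = d_z2 * w2.t();
      arma::mat d_z1 = d_a1 % (f.z1 > 0);
      arma::mat g_w1 = xb.t() * d_z1 + lam_ep * penalty_grad(w1, l21);

      ++t_step;
      opt_w1.step(w1, g_w1, lr, beta1, beta2, epsilon, t_step);
      opt_w2.step(w2, g_w2, lr, beta1, beta2, epsilon, t_step);
      if (use_bias) {
        arma::mat g_b1 = arma::sum(d_z1, 0);
        arma::mat g_b2 = arma::sum(d_z2, 0);
        arma::mat b1m(b1v), b2m(b2v);
        opt_b1.step(b1m, g_b1, lr, beta1, beta2, epsilon, t_step);
        opt_b2.step(b2m, g_b2, lr, beta1, beta2, epsilon, t_step);
        b1v = b1m.row(0);
        b2v = b2m.row(0);
      }
    }
    double tl = objective(xtr, w1, w2, b1v, b2v, use_bias, lambda, l21);
    double vl = n_val > 0
      ? objective(xval, w1, w2, b1v, b2v, use_bias, lambda, l21) : tl;
    train_loss[ep - 1] = tl;
    val_loss[ep - 1] = vl;
    if (!std::isfinite(tl) || !std::isfinite(vl))
      stop("non-finite loss at epoch %d; lower the learning rate or check "
           "the input scaling", ep);
    if (vl < best) {
      best = vl;
      best_epoch = ep;
      best_w1 = w1; best_w2 = w2; best_b1 = b1v; best_b2 = b2v;
    }
    if (ep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List model = List::create(
    _["W1"] = best_w1, _["W2"] = best_w2, _["d"] = d, _["h"] = h,
    _["use_bias"] = use_bias);
  if (use_bias) {
    model["b1"] = NumericVector(best_b1.begin(), best_b1.end());
    model["b2"] = NumericVector(best_b2.begin(), best_b2.end());
  }
  return List::create(
    _["model"] = model,
    _["train_loss"] = train_loss,
    _["val_loss"] = val_loss,
    _["best_epoch"] = best_epoch);
}
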