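// Minibatch training core for the three-hidden-layer binary MLP:
// ReLU activations, inverted dropout on the last hidden layer,
// sigmoid output with cross-entropy loss, Adam updates.
// All randomness (init, shuffling, dropout) is drawn from R's RNG so
// fits are exactly reproducible under set.seed()/withr::with_seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat relu(const arma::mat& z) {
  return arma::clamp(z, 0.0, arma::datum::inf);
}

struct AdamState {
  arma::mat m, v;
  AdamState(arma::uword r, arma::uword c)
    : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
};

static inline void adam_update(arma::mat& par, const arma::mat& g,
                               AdamState& st, double lr, int t,
                               double b1 = 0.9, double b2 = 0.999,
                               double eps = 1e-8) {
  st.m = b1 * st.m + (1.0 - b1) * g;
  st.v = b2 * st.v + (1.0 - b2) * arma::square(g);
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  par -= lr * (st.m / c1) / (arma::sqrt(st.v / c2) + eps);
}

// He-initialized weight matrix drawn from R's RNG (column-major fill,
// fixed order => reproducible).
static arma::mat he_init(arma::uword fan_in, arma::uword fan_out) {
  arma::mat w(fan_in, fan_out);
  const double sd = std::sqrt(2.0 / (double)fan_in);
  for (arma::uword j = 0; j < fan_out; ++j)
    for (arma::uword i = 0; i < fan_in; ++i)
      w(i, j) = norm_rand() * sd;
  return w;
}

// [[Rcpp::export(name = ".nn_fit_cpp")]]
List nn_fit_cpp(const arma::mat& x, const arma::vec& y,
                const IntegerVector& hidden, double lr, int epochs,
                int batch_size, double dropout) {
  const arma::uword n = x.n_rows, p = x.n_cols;
  const arma::uword h1 = hidden[0], h2 = hidden[1], h3 = hidden[2];
  const double keep = 1.0 - dropout;

  arma::mat W1 = he_init(p, h1), W2 = he_init(h1, h2),
            W3 = he_init(h2, h3), W4 = he_init(h3, 1);
  arma::rowvec b1(h1, arma::fill::zeros), b2(h2, arma::fill::zeros),
               b3(h3, arma::fill::zeros), b4(1, arma::fill::zeros);

  AdamState sW1(p, h1), sW2(h1, h2), sW3(h2, h3), sW4(h3, 1);
  AdamState sb1(1, h1), sb2(1, h2), sb3(1, h3), sb4(1, 1);

  int t = 0;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle via R's RNG
    arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(unif_rand() * (double)(i + 1));
      if (j > i) j = i;
      std::swap(ord(i), ord(j));
    }
    for (arma::uword s = 0; s < n; s += batch_size) {
      const arma::uword e = std::min<arma::uword>(s + batch_size, n);
      const arma::uvec idx = ord.subvec(s, e - 1);
      const arma::mat xb = x.rows(idx);
      const arma::vec yb = y.elem(idx);
      const double nb = (double)idx.n_elem;

      arma::mat a1 = relu(xb * W1 + arma::ones(idx.n_elem) * b1);
      arma::mat a2 = relu(a1 * W2 + arma::ones(idx.n_elem) * b2);
      arma::mat a3 = relu(a2 * W3 + arma::ones(idx.n_elem) * b3);
      arma::mat mask;
      if (keep < 1.0) {
        mask.set_size(a3.n_rows, a3.n_cols);
        for (arma::uword j = 0; j < mask.n_cols; ++j)
          for (arma::uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        a3 %= mask;
      }
      arma::vec z = a3 * W4 + b4(0);
      arma::vec prob = 1.0 / (1.0 + arma::exp(-z));

      arma::mat d4 = (prob - yb) / nb;                 // n x 1
      arma::mat gW4 = a3.t() * d4;
      arma::rowvec gb4 = arma::sum(d4, 0);
      arma::mat d3 = d4 * W4.t();
      if (keep < 1.0) d3 %= mask;
      d3 %= arma::conv_to<arma::mat>::from(a3 > 0);
      arma::mat gW3 = a2.t() * d3;
      arma::rowvec gb3 = arma::sum(d3, 0);
      arma::mat d2 = (d3 * W3.t()) % arma::conv_to<arma::mat>::from(a2 > 0);
      arma::mat gW2 = a1.t() * d2;
      arma::rowvec gb2 = arma::sum(d2, 0);
      arma::mat d1 = (d2 * W2.t()) % arma::conv_to<arma::mat>::from(a1 > 0);
      arma::mat gW1 = xb.t() * d1;
      arma::rowvec gb1 = arma::sum(d1, 0);

      ++t;
      adam_update(W1, gW1, sW1, lr, t);
      adam_update(W2, gW2, sW2, lr, t);
      adam_update(W3, gW3, sW3, lr, t);
      adam_update(W4, gW4, sW4, lr, t);
      arma::mat b;
      b = b1; adam_update(b, gb1, sb1, lr, t); b1 = b.row(0);
      b = b2; adam_update(b, gb2, sb2, lr, t); b2 = b.row(0);
      b = b3; adam_update(b, gb3, sb3, lr, t); b3 = b.row(0);
      b = b4; adam_update(b, gb4, sb4, lr, t); b4 = b.row(0);
    }
  }
  return List::create(
    Named("W") = List::create(W1, W2, W3, W4),
    Named("b") = List::create(NumericVector(b1.begin(), b1.end()),
                              NumericVector(b2.begin(), b2.end()),
                              NumericVector(b3.begin(), b3.end()),
                              NumericVector(b4.begin(), b4.end())));
}

// [[Rcpp::export(name = ".nn_predict_cpp")]]
arma::vec nn_predict_cpp(const List& W, const List& b,
                         const arma::mat& x) {
  arma::mat W1 = W[0], W2 = W[1], W3 = W[2], W4 = W[3];
  arma::rowvec b1 = as<arma::rowvec>(b[0]), b2 = as<arma::rowvec>(b[1]),
               b3 = as<arma::rowvec>(b[2]), b4 = as<arma::rowvec>(b[3]);
  arma::mat a1 = relu(x * W1 + arma::ones(x.n_rows) * b1);
  arma::mat a2 = relu(a1 * W2 + arma::ones(x.n_rows) * b2);
  arma::mat a3 = relu(a2 * W3 + arma::ones(x.n_rows) * b3);
  arma::vec z = a3 * W4 + b4(0);
  return 1.0 / (1.0 + arma::exp(-z));
}
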