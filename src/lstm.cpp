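#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Single-direction LSTM over a sequence.
//
// X  : D x n input columns.
// W  : 4h x D input weights, U : 4h x h recurrent weights, b : 4h bias.
// Gate order within the stacked 4h rows: input, forget, output, candidate.
// h0, c0 : h initial states.
//
// Returns H (h x n hidden outputs), C (h x n cell states) and the
// post-activation gates G (4h x n) needed for backpropagation.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::mat& X, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            const arma::vec& h0, const arma::vec& c0) {
  const uword n = X.n_cols, h = U.n_cols;
  mat H(h, n), C(h, n), G(4 * h, n);
  vec hp = h0, cp = c0;
  for (uword t = 0; t < n; ++t) {
    vec z = W * X.col(t) + U * hp + b;
    vec gi = 1.0 / (1.0 + exp(-z.subvec(0, h - 1)));
    vec gf = 1.0 / (1.0 + exp(-z.subvec(h, 2 * h - 1)));
    vec go = 1.0 / (1.0 + exp(-z.subvec(2 * h, 3 * h - 1)));
    vec gg = tanh(z.subvec(3 * h, 4 * h - 1));
    vec c = gf % cp + gi % gg;
    vec hh = go % tanh(c);
    G(span(0, h - 1), span(t, t)) = gi;
    G(span(h, 2 * h - 1), span(t, t)) = gf;
    G(span(2 * h, 3 * h - 1), span(t, t)) = go;
    G(span(3 * h, 4 * h - 1), span(t, t)) = gg;
    C.col(t) = c;
    H.col(t) = hh;
    hp = hh;
    cp = c;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("G") = G);
}

// Backpropagation through time for cpp_lstm_forward.
//
// dH : h x n upstream gradient on the hidden outputs; dh_last/dc_last are
// extra gradients flowing into the final hidden/cell state (zero vectors
// when unused). Returns gradients for X, W, U, b and the initial states.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::mat& X, const arma::mat& W,
                             const arma::mat& U, const arma::mat& H,
                             const arma::mat& C, const arma::mat& G,
                             const arma::vec& h0, const arma::vec& c0,
                             const arma::mat& dH, const arma::vec& dh_last,
                             const arma::vec& dc_last) {
  const uword n = X.n_cols, h = U.n_cols, D = X.n_rows;
  mat dX(D, n, fill::zeros), dW(4 * h, D, fill::zeros),
      dU(4 * h, h, fill::zeros);
  vec db(4 * h, fill::zeros);
  vec dh_next(h, fill::zeros), dc_next(h, fill::zeros);
  for (uword tt = n; tt-- > 0;) {
    vec gi = G(span(0, h - 1), span(tt, tt));
    vec gf = G(span(h, 2 * h - 1), span(tt, tt));
    vec go = G(span(2 * h, 3 * h - 1), span(tt, tt));
    vec gg = G(span(3 * h, 4 * h - 1), span(tt, tt));
    vec c = C.col(tt);
    vec cp = (tt == 0) ? c0 : vec(C.col(tt - 1));
    vec hp = (tt == 0) ? h0 : vec(H.col(tt - 1));
    vec tc = tanh(c);
    vec dh = dH.col(tt) + dh_next;
    if (tt == n - 1) dh += dh_last;
    vec dc = dc_next + dh % go % (1.0 - tc % tc);
    if (tt == n - 1) dc += dc_last;
    vec dgo = dh % tc;
    vec dgi = dc % gg;
    vec dgf = dc % cp;
    vec dgg = dc % gi;
    vec dz = join_cols(join_cols(dgi % gi % (1.0 - gi), dgf % gf % (1.0 - gf)),
                       join_cols(dgo % go % (1.0 - go), dgg % (1.0 - gg % gg)));
    dW += dz * X.col(tt).t();
    dU += dz * hp.t();
    db += dz;
    dX.col(tt) = W.t() * dz;
    dh_next = U.t() * dz;
    dc_next = dc % gf;
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW, Rcpp::Named("dU") = dU,
      Rcpp::Named("db") = db, Rcpp::Named("dh0") = dh_next,
      Rcpp::Named("dc0") = dc_next);
}
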