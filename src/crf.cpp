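#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Linear-chain CRF with START/STOP augmentation.
//
// Emissions P are n x K (row per position, column per tag).  The transition
// matrix T is (K+2) x (K+2) with 0-based tag indices 0..K-1, START = K,
// STOP = K+1; T(a, b) scores moving from tag a to tag b.  Structural
// impossibilities (into START, out of STOP) may hold -inf; the recursions
// below only touch legal entries.

static inline double logsumexp(const vec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(v - m)));
}

// Log partition function via the forward recursion in log space.
// [[Rcpp::export]]
double cpp_crf_log_partition(const arma::mat& P, const arma::mat& T) {
  const uword n = P.n_rows, K = P.n_cols;
  const uword START = K, STOP = K + 1;
  vec a = T.submat(START, 0, START, K - 1).t() + P.row(0).t();
  for (uword t = 1; t < n; ++t) {
    vec anew(K);
    for (uword j = 0; j < K; ++j)
      anew(j) = logsumexp(a + T.submat(0, j, K - 1, j)) + P(t, j);
    a = anew;
  }
  return logsumexp(a + T.submat(0, STOP, K - 1, STOP));
}

// Forward-backward: gradients of log Z with respect to emissions (the
// per-position tag marginals) and to the transition matrix (expected
// transition counts, including START/STOP rows/columns).
// [[Rcpp::export]]
Rcpp::List cpp_crf_grads(const arma::mat& P, const arma::mat& T) {
  const uword n = P.n_rows, K = P.n_cols;
  const uword START = K, STOP = K + 1;
  mat alpha(n, K), beta(n, K);
  const mat Tin0 = T.submat(0, 0, K - 1, K - 1);
  alpha.row(0) = (T.submat(START, 0, START, K - 1).t() + P.row(0).t()).t();
  for (uword t = 1; t < n; ++t) {
    // column j of M holds alpha(t-1, i) + T(i, j); log-sum-exp columnwise
    mat M = Tin0;
    M.each_col() += alpha.row(t - 1).t();
    rowvec m = max(M, 0);
    alpha.row(t) = m + log(sum(exp(M.each_row() - m), 0)) + P.row(t);
  }
  // Backward pass, fused with the expected-transition-count accumulation:
  // with E_t = exp(M_t - m) for M_t(i,j) = T(i,j) + P(t+1,j) + beta(t+1,j)
  // and rowwise max m, beta(t) = m + log(rowsum(E_t)) and the pairwise
  // marginal at t is E_t scaled by exp(alpha(t,i) + m_i - logZ).  logZ is
  // needed first, so compute it from alpha alone.
  double logZ =
      logsumexp(alpha.row(n - 1).t() + T.submat(0, STOP, K - 1, STOP));
  beta.row(n - 1) = T.submat(0, STOP, K - 1, STOP).t();
  mat dT(K + 2, K + 2, fill::zeros);
  mat dTin(K, K, fill::zeros);
  for (uword t = n - 1; t-- > 0;) {
    mat M = Tin0;
    M.each_row() += P.row(t + 1) + beta.row(t + 1);
    vec m = max(M, 1);
    mat E = exp(M.each_col() - m);
    beta.row(t) = (m + log(sum(E, 1))).t();
    dTin += E.each_col() % exp(alpha.row(t).t() + m - logZ);
  }
  dT.submat(0, 0, K - 1, K - 1) = dTin;

  mat dP = exp(alpha + beta - logZ);
  for (uword j = 0; j < K; ++j)
    dT(START, j) = std::exp(T(START, j) + P(0, j) + beta(0, j) - logZ);
  for (uword i = 0; i < K; ++i)
    dT(i, STOP) = std::exp(alpha(n - 1, i) + T(i, STOP) - logZ);

  return Rcpp::List::create(Rcpp::Named("logZ") = logZ,
                            Rcpp::Named("dP") = dP, Rcpp::Named("dT") = dT);
}

// Viterbi decoding; ties break toward the lowest tag index (strict '>' when
// scanning candidates in increasing index order).  Returns the 1-based path
// and its score.
// [[Rcpp::export]]
Rcpp::List cpp_crf_viterbi(const arma::mat& P, const arma::mat& T) {
  const uword n = P.n_rows, K = P.n_cols;
  const uword START = K, STOP = K + 1;
  mat delta(n, K);
  umat psi(n, K, fill::zeros);
  delta.row(0) = (T.submat(START, 0, START, K - 1).t() + P.row(0).t()).t();
  for (uword t = 1; t < n; ++t) {
    for (uword j = 0; j < K; ++j) {
      double best = -datum::inf;
      uword arg = 0;
      for (uword i = 0; i < K; ++i) {
        double s = delta(t - 1, i) + T(i, j);
        if (s > best) { best = s; arg = i; }
      }
      delta(t, j) = best + P(t, j);
      psi(t, j) = arg;
    }
  }
  double best = -datum::inf;
  uword arg = 0;
  for (uword i = 0; i < K; ++i) {
    double s = delta(n - 1, i) + T(i, STOP);
    if (s > best) { best = s; arg = i; }
  }
  uvec path(n);
  path(n - 1) = arg;
  for (uword t = n - 1; t-- > 0;) path(t) = psi(t + 1, path(t + 1));
  return Rcpp::List::create(Rcpp::Named("path") = path + 1,
                            Rcpp::Named("score") = best);
}
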