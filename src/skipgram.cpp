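#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Skip-gram with negative sampling (SGNS), single-threaded, driven by R's
// RNG so results are reproducible under set.seed().
//
// sentences : list of integer vectors, 1-based token ids in 1..V.
// neg_cdf   : cumulative distribution over 1..V for negative sampling
//             (unigram counts raised to 3/4, normalised, cumsum'd).
// Learning rate decays linearly from lr to lr * 1e-4 over all training
// pairs.  Returns the input-side embedding matrix, D x V.
// [[Rcpp::export]]
arma::mat cpp_skipgram(const Rcpp::List& sentences, int V, int D, int window,
                       int negatives, int epochs, double lr,
                       const arma::vec& neg_cdf) {
  mat Win(D, V), Wout(D, V, fill::zeros);
  // word2vec-style init: uniform in (-0.5/D, 0.5/D)
  for (uword j = 0; j < (uword)V; ++j)
    for (uword i = 0; i < (uword)D; ++i)
      Win(i, j) = (unif_rand() - 0.5) / D;

  // total center-context pairs for the lr schedule
  long long total = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    Rcpp::IntegerVector sen = sentences[s];
    int len = sen.size();
    for (int c = 0; c < len; ++c) {
      int lo = std::max(0, c - window), hi = std::min(len - 1, c + window);
      total += hi - lo;
    }
  }
  total *= epochs;
  if (total == 0) return Win;

  const double lr_min = lr * 1e-4;
  long long seen = 0;
  vec err(D);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      Rcpp::IntegerVector sen = sentences[s];
      int len = sen.size();
      for (int c = 0; c < len; ++c) {
        int center = sen[c] - 1;
        int lo = std::max(0, c - window), hi = std::min(len - 1, c + window);
        for (int k = lo; k <= hi; ++k) {
          if (k == c) continue;
          double a = lr - (lr - lr_min) * ((double)seen / (double)total);
          ++seen;
          int ctx = sen[k] - 1;
          err.zeros();
          // one positive + `negatives` sampled targets
          for (int m = 0; m <= negatives; ++m) {
            int target;
            double label;
            if (m == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = unif_rand();
              // inverse-CDF sample; binary search over neg_cdf
              uword lo2 = 0, hi2 = V - 1;
              while (lo2 < hi2) {
                uword mid = (lo2 + hi2) / 2;
                if (neg_cdf(mid) < u) lo2 = mid + 1; else hi2 = mid;
              }
              target = (int)lo2;
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = dot(Win.col(center), Wout.col(target));
            double g = (label - 1.0 / (1.0 + std::exp(-f))) * a;
            err += g * Wout.col(target);
            Wout.col(target) += g * Win.col(center);
          }
          Win.col(center) += err;
        }
      }
    }
  }
  return Win;
}
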