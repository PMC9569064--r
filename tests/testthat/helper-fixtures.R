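# Shared test fixtures: tiny deterministic embedding tables, random CRF
# instances with a brute-force enumeration oracle, and small corpora.

# deterministic embedding table over given characters
tiny_embeddings <- function(chars, dim = 4L, seed = 1L, sd = 0.3) {
  set.seed(seed)
  W <- matrix(stats::rnorm(dim * length(chars), sd = sd), dim,
              length(chars), dimnames = list(NULL, chars))
  structure(list(vectors = W, dim = as.integer(dim), seed = as.integer(seed)),
            class = "embedding_table")
}

# random CRF instance: emissions n x K plus transitions with random legal
# entries (structural -Inf untouched)
random_crf <- function(n, K, sd = 1) {
  P <- matrix(stats::rnorm(n * K, sd = sd), n, K)
  T_ <- make_transitions(K)
  T_[1:K, 1:K] <- stats::rnorm(K * K, sd = sd)
  T_[K + 1L, 1:K] <- stats::rnorm(K, sd = sd)
  T_[1:K, K + 2L] <- stats::rnorm(K, sd = sd)
  list(P = P, T = T_)
}

# all K^n tag paths, one row each
all_paths <- function(n, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), n)))
}

# vectorised brute-force path scores over all paths
enumerate_scores <- function(P, T_) {
  n <- nrow(P); K <- ncol(P)
  paths <- all_paths(n, K)
  s <- T_[K + 1L, paths[, 1L]] + T_[cbind(paths[, n], K + 2L)]
  for (t in seq_len(n)) s <- s + P[t, paths[, t]]
  if (n > 1L) {
    for (t in seq_len(n - 1L)) s <- s + T_[cbind(paths[, t], paths[, t + 1L])]
  }
  list(paths = paths, scores = s)
}

# small synthetic world for fast end-to-end style tests
small_world <- function(seed = 7L, sizes = c(30L, 6L, 8L)) {
  generator_config(split_sizes = sizes, length_range = c(40L, 70L),
                   seed = seed)
}
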