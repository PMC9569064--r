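#' Linear-chain CRF scoring primitives
#'
#' The CRF scores a tag path `y` over `n` positions as
#' `s(X, y) = sum_i T[y_i, y_{i+1}] + sum_i P[i, y_i]` under the
#' START/STOP augmentation convention (`y_0 = START`, `y_{n+1} = STOP`),
#' where `P` is the `n x K` emission matrix and `T` the
#' `(K+2) x (K+2)` transition matrix with rows/columns `K+1 = START`,
#' `K+2 = STOP`.  Entries into START and out of STOP are structurally
#' `-Inf`.
#'
#' @param n_tags Number of real tags K.
#' @return `make_transitions()` returns the zero-initialised transition
#'   matrix with its structural `-Inf` entries set.
#' @export
make_transitions <- function(n_tags) {
  K <- as.integer(n_tags)
  T_ <- matrix(0, K + 2L, K + 2L)
  T_[, K + 1L] <- -Inf   # nothing moves into START
  T_[K + 2L, ] <- -Inf   # nothing moves out of STOP
  T_
}

#' @rdname make_transitions
#' @param hidden `n x 2h` matrix of BiLSTM hidden states (row per
#'   position).
#' @param W_e `K x 2h` emission weight matrix.
#' @return `emission_scores()` returns the `n x K` matrix
#'   `tanh(hidden %*% t(W_e))`; every entry lies in (-1, 1).
#' @export
emission_scores <- function(hidden, W_e) {
  tanh(hidden %*% t(W_e))
}

#' @rdname make_transitions
#' @param emissions `n x K` emission matrix.
#' @param trans `(K+2) x (K+2)` transition matrix.
#' @param path Integer vector of tag indices in `1..K`, length `n`.
#' @return `path_score()` returns the scalar path score.
#' @export
path_score <- function(emissions, trans, path) {
  n <- nrow(emissions); K <- ncol(emissions)
  stopifnot(length(path) == n, all(path >= 1L), all(path <= K))
  s <- trans[K + 1L, path[1L]] + trans[path[n], K + 2L] +
    sum(emissions[cbind(seq_len(n), path)])
  if (n > 1L) s <- s + sum(trans[cbind(path[-n], path[-1L])])
  s
}

#' @rdname make_transitions
#' @return `log_partition()` returns `log sum_y exp(s(X, y))` over all
#'   `K^n` paths, computed by the forward recursion in log space.
#' @export
log_partition <- function(emissions, trans) {
  cpp_crf_log_partition(emissions, trans)
}

#' @rdname make_transitions
#' @return `path_log_probability()` returns
#'   `path_score() - log_partition()`, which is `<= 0`.
#' @export
path_log_probability <- function(emissions, trans, path) {
  path_score(emissions, trans, path) - log_partition(emissions, trans)
}

#' @rdname make_transitions
#' @return `viterbi()` returns a `tag_path`: list with the argmax `path`
#'   (1-based tag indices), its `score` and its `log_probability`.  Ties
#'   break toward the lowest tag index.
#' @export
viterbi <- function(emissions, trans) {
  v <- cpp_crf_viterbi(emissions, trans)
  structure(list(path = as.integer(v$path), score = v$score,
                 log_probability = v$score -
                   cpp_crf_log_partition(emissions, trans)),
            class = "tag_path")
}
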