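#' Pretrain character embeddings with skip-gram
#'
#' Trains skip-gram with negative sampling over the character sequences of
#' an (unlabeled) corpus.  When a risk-factor lexicon is supplied, each
#' surface form is appended as an extra training sentence, repeated
#' `lexicon_repeats` times — the dictionary-augmentation step that boosts
#' co-occurrence between characters of the same risk-factor term.
#' Training is single-threaded and fully determined by `seed`.
#'
#' @param corpus List of [emr_document()] objects, or a list of character
#'   vectors.
#' @param risk_lexicon Optional data frame with a `surface` column (see
#'   [default_risk_lexicon()]).
#' @param dim Embedding dimension D (default 100).
#' @param window Context window half-width.
#' @param negatives Negative samples per positive pair.
#' @param epochs Training epochs.
#' @param min_count Minimum corpus frequency for a character to receive a
#'   vector (characters below it fall back to the OOV vector).
#' @param lr Initial learning rate.
#' @param lexicon_repeats How many times each lexicon surface form is
#'   appended as a sentence.
#' @param seed Integer seed.
#' @return An `embedding_table`: list with `vectors` (D x V matrix, one
#'   named column per character), `dim`, and `seed`.  Lookup of an unseen
#'   character returns the zero OOV vector.
#' @export
train_char_embeddings <- function(corpus, risk_lexicon = NULL, dim = 100L,
                                  window = 5L, negatives = 5L, epochs = 5L,
                                  min_count = 1L, lr = 0.025,
                                  lexicon_repeats = 5L, seed = 1L) {
  stopifnot(length(corpus) > 0L, dim >= 1L)
  sents <- lapply(corpus, function(d)
    if (inherits(d, "emr_document")) d$chars else d)
  if (!is.null(risk_lexicon)) {
    extra <- rep(risk_lexicon$surface, each = lexicon_repeats)
    sents <- c(sents, lapply(extra, function(s)
      strsplit(s, "", fixed = TRUE)[[1L]]))
  }
  counts <- table(unlist(sents))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) == 0L) stop("corpus has no characters above min_count",
                                call. = FALSE)
  vocab <- sort(vocab)  # deterministic ordering
  ids <- lapply(sents, function(s) {
    i <- match(s, vocab)
    i[!is.na(i)]
  })
  ids <- ids[vapply(ids, length, 0L) > 0L]
  freq <- as.numeric(counts[vocab])^0.75
  cdf <- cumsum(freq / sum(freq))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  W <- cpp_skipgram(ids, length(vocab), as.integer(dim),
                    as.integer(window), as.integer(negatives),
                    as.integer(epochs), lr, cdf)
  colnames(W) <- vocab
  structure(list(vectors = W, dim = as.integer(dim), seed = as.integer(seed)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", ncol(x$vectors), " characters, D = ", x$dim,
      "\n", sep = "")
  invisible(x)
}

#' Look up the vector of a character
#'
#' Total function: characters absent from the table map to the zero OOV
#' vector, which contributes neutrally to averages.
#'
#' @param table An `embedding_table`.
#' @param char A single character.
#' @return Numeric vector of length `table$dim`.
#' @export
lookup <- function(table, char) {
  stopifnot(inherits(table, "embedding_table"), length(char) == 1L)
  j <- match(char, colnames(table$vectors))
  if (is.na(j)) numeric(table$dim) else unname(table$vectors[, j])
}

#' Embedding of a multi-character word
#'
#' The arithmetic mean of the word's character vectors (OOV characters
#' contribute zero vectors), used to embed risk-factor surface forms.
#'
#' @param table An `embedding_table`.
#' @param word Non-empty string.
#' @return Numeric vector of length `table$dim`.
#' @export
word_embedding <- function(table, word) {
  stopifnot(length(word) == 1L)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty word", call. = FALSE)
  vs <- vapply(chars, function(ch) lookup(table, ch),
               numeric(table$dim))
  rowMeans(matrix(vs, nrow = table$dim))
}

#' Save and load embedding tables in word2vec text format
#'
#' Header line `<count> <dim>`, then one line per character: the token
#' followed by D floats, space-separated.
#'
#' @param table An `embedding_table`.
#' @param path File path.
#' @return `load_embeddings()` returns an `embedding_table`;
#'   `save_embeddings()` returns `path` invisibly.
#' @export
save_embeddings <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(ncol(table$vectors), table$dim), con)
  for (j in seq_len(ncol(table$vectors))) {
    writeLines(paste(colnames(table$vectors)[j],
                     paste(sprintf("%.17g", table$vectors[, j]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hd <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  V <- hd[1L]; D <- hd[2L]
  W <- matrix(0, nrow = D, ncol = V)
  toks <- character(V)
  for (j in seq_len(V)) {
    parts <- strsplit(lines[j + 1L], " ", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    toks[j] <- parts[1L]
    W[, j] <- as.numeric(parts[-1L])
  }
  colnames(W) <- toks
  structure(list(vectors = W, dim = D, seed = NA_integer_),
            class = "embedding_table")
}
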