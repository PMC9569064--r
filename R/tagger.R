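#' Configuration of the BiLSTM-CRF risk-factor tagger
#'
#' Hyperparameters are shared with the document classifier: embedding
#' dimension 100, hidden units 256 per direction, learning rate 1e-3
#' (Adagrad) decayed by 0.99 every 500 steps, batch size 10, dropout 0.5
#' on the embedding layer, 60 epochs.
#'
#' @param embedding_dim Character embedding dimension D.
#' @param hidden Hidden units per LSTM direction.
#' @param vocab Tag vocabulary ([build_tag_vocabulary()]).
#' @param lr,batch_size,epochs,dropout,decay_rate,decay_steps Optimiser
#'   settings.
#' @param warmup_steps Linear learning-rate warm-up horizon in optimiser
#'   steps (0 = off); limits early emission-layer saturation.
#' @param seed Integer seed driving initialisation, dropout and shuffling.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(embedding_dim = 100L, hidden = 256L,
                          vocab = build_tag_vocabulary(), lr = 1e-3,
                          batch_size = 10L, epochs = 60L, dropout = 0.5,
                          decay_rate = 0.99, decay_steps = 500L,
                          warmup_steps = 0L, seed = 1L) {
  stopifnot(embedding_dim >= 1L, hidden >= 1L, lr > 0, batch_size >= 1L,
            epochs >= 1L, dropout >= 0, dropout < 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden = as.integer(hidden), vocab = vocab, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 warmup_steps = as.integer(warmup_steps),
                 seed = as.integer(seed)),
            class = "tagger_config")
}

# trainable parameters; E holds one column per known character plus a
# trainable OOV column (initialised to zero, matching the OOV contract)
init_tagger_params <- function(config, embeddings) {
  stopifnot(config$embedding_dim == embeddings$dim)
  h <- config$hidden
  K <- length(config$vocab$tags)
  char_vocab <- c(colnames(embeddings$vectors), "<OOV>")
  E <- cbind(embeddings$vectors, 0)
  colnames(E) <- char_vocab
  fw <- lstm_params(config$embedding_dim, h)
  bw <- lstm_params(config$embedding_dim, h)
  list(E = E,
       Wf = fw$W, Uf = fw$U, bf = fw$b,
       Wb = bw$W, Ub = bw$U, bb = bw$b,
       We = glorot(K, 2L * h),
       trans = bio_prior_transitions(config$vocab))
}

# Soft BIO-structure initialisation of the transition matrix: an I- tag is
# strongly (but not infinitely) dispreferred unless it continues its own
# B-/I- run.  This is an initialisation only -- every entry remains a free,
# learned parameter -- and it shortens the early phase in which the
# partition function spreads mass over grammatically impossible paths.
bio_prior_transitions <- function(vocab, penalty = -4) {
  K <- length(vocab$tags)
  T_ <- make_transitions(K)
  is_i <- startsWith(vocab$tags, "I-")
  lab <- sub("^[BI]-", "", vocab$tags)
  for (j in which(is_i)) {
    # allowed predecessors of I-L are exactly B-L and I-L
    T_[1:K, j] <- ifelse(lab == lab[j], 0, penalty)
    T_[K + 1L, j] <- penalty          # paths should not open with I
  }
  T_
}

char_ids <- function(chars, char_vocab) {
  i <- match(chars, char_vocab)
  i[is.na(i)] <- length(char_vocab)  # <OOV>
  i
}

#' Encode a character sequence with a bidirectional LSTM
#'
#' Embeds each character by table lookup and runs forward and backward
#' LSTM passes (zero initial states); position `t`'s representation is the
#' concatenation `[h_t_fwd ; h_t_bwd]` carrying left and right context.
#'
#' @param chars Character vector (non-empty).
#' @param embeddings An `embedding_table`.
#' @param params List with LSTM weights `Wf, Uf, bf, Wb, Ub, bb` (see
#'   internals of [train_tagger()]); input dimension must equal
#'   `embeddings$dim`.
#' @return `n x 2h` matrix of hidden states.
#' @export
encode <- function(chars, embeddings, params) {
  if (length(chars) == 0L) stop("empty character sequence", call. = FALSE)
  X <- vapply(chars, function(ch) lookup(embeddings, ch),
              numeric(embeddings$dim))
  X <- matrix(X, nrow = embeddings$dim)
  bilstm_states(X, params)
}

# X is D x n; returns n x 2h row-per-position states
bilstm_states <- function(X, params) {
  n <- ncol(X)
  h <- ncol(params$Uf)
  z <- numeric(h)
  fw <- cpp_lstm_forward(X, params$Wf, params$Uf, params$bf, z, z)
  bw <- cpp_lstm_forward(X[, n:1, drop = FALSE], params$Wb, params$Ub,
                         params$bb, z, z)
  t(rbind(fw$H, bw$H[, n:1, drop = FALSE]))
}

# full forward pass with caches for backprop
tagger_forward <- function(params, ids, dropout = 0, training = FALSE) {
  n <- length(ids)
  h <- ncol(params$Uf)
  X <- params$E[, ids, drop = FALSE]
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(stats::rbinom(length(X), 1L, 1 - dropout) / (1 - dropout),
                   nrow(X), ncol(X))
    X <- X * mask
  }
  z <- numeric(h)
  fw <- cpp_lstm_forward(X, params$Wf, params$Uf, params$bf, z, z)
  Xr <- X[, n:1, drop = FALSE]
  bw <- cpp_lstm_forward(Xr, params$Wb, params$Ub, params$bb, z, z)
  Ht <- t(rbind(fw$H, bw$H[, n:1, drop = FALSE]))
  emis <- tanh(Ht %*% t(params$We))
  list(X = X, Xr = Xr, mask = mask, fw = fw, bw = bw, Ht = Ht, emis = emis,
       n = n, h = h)
}

# negative log-likelihood of the gold path and its analytic gradients
tagger_doc_grads <- function(params, ids, gold, dropout = 0) {
  fwd <- tagger_forward(params, ids, dropout, training = TRUE)
  n <- fwd$n; h <- fwd$h
  K <- nrow(params$We)
  cg <- cpp_crf_grads(fwd$emis, params$trans)
  gold_score <- path_score(fwd$emis, params$trans, gold)
  loss <- cg$logZ - gold_score
  demis <- cg$dP
  demis[cbind(seq_len(n), gold)] <- demis[cbind(seq_len(n), gold)] - 1
  dtrans <- cg$dT
  dtrans[K + 1L, gold[1L]] <- dtrans[K + 1L, gold[1L]] - 1
  dtrans[gold[n], K + 2L] <- dtrans[gold[n], K + 2L] - 1
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      dtrans[gold[t], gold[t + 1L]] <- dtrans[gold[t], gold[t + 1L]] - 1
    }
  }
  dpre <- demis * (1 - fwd$emis^2)
  dWe <- t(dpre) %*% fwd$Ht
  dHt <- dpre %*% params$We
  z <- numeric(h)
  gf <- cpp_lstm_backward(fwd$X, params$Wf, params$Uf, fwd$fw$H, fwd$fw$C,
                          fwd$fw$G, z, z, t(dHt[, 1:h, drop = FALSE]), z, z)
  dHb <- t(dHt[, (h + 1L):(2L * h), drop = FALSE])[, n:1, drop = FALSE]
  gb <- cpp_lstm_backward(fwd$Xr, params$Wb, params$Ub, fwd$bw$H, fwd$bw$C,
                          fwd$bw$G, z, z, dHb, z, z)
  dX <- gf$dX + gb$dX[, n:1, drop = FALSE]
  if (!is.null(fwd$mask)) dX <- dX * fwd$mask
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  for (t in seq_len(n)) dE[, ids[t]] <- dE[, ids[t]] + dX[, t]
  list(loss = loss,
       grads = list(E = dE, Wf = gf$dW, Uf = gf$dU, bf = gf$db,
                    Wb = gb$dW, Ub = gb$dU, bb = gb$db,
                    We = dWe, trans = dtrans))
}

#' Train the BiLSTM-CRF tagger
#'
#' Minimises the negative log-probability of the gold tag path (the CRF
#' maximum-likelihood objective) with Adagrad.  Transition scores and all
#' network weights, including the character embeddings, are learned.
#' Per-epoch training loss and development-set entity F are recorded; the
#' parameters achieving the best development F are returned.
#'
#' @param train_docs,dev_docs Lists of annotated [emr_document()]s (every
#'   training document must carry mentions, possibly empty).
#' @param config A [tagger_config()].
#' @param embeddings Pretrained `embedding_table`
#'   ([train_char_embeddings()]).
#' @param verbose Print per-epoch progress.
#' @return A `tagger_model`: list with `params`, `config`, `history`
#'   (data frame epoch/loss/dev_f) and `char_vocab`.
#' @export
train_tagger <- function(train_docs, dev_docs, config, embeddings,
                         verbose = FALSE) {
  stopifnot(inherits(config, "tagger_config"))
  for (d in train_docs) {
    if (is.null(d$mentions)) {
      stop("training document '", d$doc_id, "' has no gold annotation",
           call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)
  params <- init_tagger_params(config, embeddings)
  char_vocab <- colnames(params$E)
  vocab <- config$vocab
  ids_list <- lapply(train_docs, function(d) char_ids(d$chars, char_vocab))
  gold_list <- lapply(train_docs, function(d)
    unname(vocab$index[to_bio(d, vocab)]))
  state <- adagrad_state(params)
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dev_f = numeric(0))
  best <- list(f = -Inf, params = params)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(train_docs))
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      acc <- NULL
      bl <- 0
      for (i in batch) {
        g <- tagger_doc_grads(params, ids_list[[i]], gold_list[[i]],
                              config$dropout)
        bl <- bl + g$loss
        acc <- if (is.null(acc)) g$grads else
          Map(`+`, acc, g$grads)
      }
      nb <- length(batch)
      acc <- lapply(acc, function(x) x / nb)
      lr_t <- decayed_lr(config$lr, config$decay_rate, config$decay_steps,
                         step, config$warmup_steps %||% 0L)
      upd <- adagrad_step(params, acc, state, lr_t)
      params <- upd$params
      state <- upd$state
      step <- step + 1L
      losses <- c(losses, bl / nb)
    }
    model_now <- structure(list(params = params, config = config,
                                char_vocab = char_vocab),
                           class = "tagger_model")
    dev_f <- if (length(dev_docs) > 0L) {
      pred <- lapply(dev_docs, function(d) extract_risk_factors(d, model_now))
      gold <- lapply(dev_docs, `[[`, "mentions")
      entity_report(gold, pred)$F
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         dev_f = dev_f))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  dev entity-F %.2f", ep,
                      mean(losses), dev_f))
    }
    if (!is.na(dev_f) && dev_f > best$f) {
      best <- list(f = dev_f, params = params)
    }
  }
  structure(list(params = if (is.finite(best$f)) best$params else params,
                 config = config, char_vocab = char_vocab,
                 history = history),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat("<tagger_model> ", length(x$config$vocab$tags), " tags, h = ",
      x$config$hidden, ", ", nrow(x$history), " epoch(s) trained\n",
      sep = "")
  invisible(x)
}

#' Predict BIO tags for a document
#'
#' Runs the trained network and Viterbi-decodes the best tag path.
#'
#' @param model A `tagger_model`.
#' @param doc An [emr_document()].
#' @return Character vector of predicted tags.
#' @export
predict_tags <- function(model, doc) {
  ids <- char_ids(doc$chars, model$char_vocab)
  fwd <- tagger_forward(model$params, ids)
  v <- viterbi(fwd$emis, model$params$trans)
  model$config$vocab$tags[v$path]
}

#' Extract risk-factor mentions from a document
#'
#' Viterbi-decodes the tagger's output and converts the BIO sequence back
#' to entity mentions (applying IOB2 repair to any ill-formed runs).
#'
#' @param doc An [emr_document()].
#' @param model A `tagger_model`.
#' @return List of [entity_mention()] objects.
#' @export
extract_risk_factors <- function(doc, model) {
  tags <- predict_tags(model, doc)
  from_bio(doc$chars, tags, model$config$vocab)
}

#' Save or load a tagger checkpoint
#'
#' A checkpoint is a single archive holding the weights, the
#' configuration (including the tag vocabulary) and the character
#' vocabulary.
#'
#' @param model A `tagger_model`.
#' @param path File path.
#' @return `load_tagger()` returns the model; `save_tagger()` the path,
#'   invisibly.
#' @export
save_tagger <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) readRDS(path)
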