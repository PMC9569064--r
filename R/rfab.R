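#' Configuration of the RFAB document classifier
#'
#' Defaults are the shared hyperparameter table: embedding dimension
#' `d_w = 100`, learning rate `1e-3` (Adagrad) with decay rate 0.99 every
#' 500 steps, batch size 10, dropout 0.5 at the end of the embedding
#' layer, 256 hidden units per BiLSTM direction, 60 epochs.
#'
#' @param embedding_dim Character/factor embedding dimension D.
#' @param hidden Hidden units per BiLSTM direction.
#' @param lr,batch_size,epochs,dropout,decay_rate,decay_steps Optimiser
#'   settings.
#' @param warmup_steps Linear learning-rate warm-up horizon in optimiser
#'   steps (0 = off).
#' @param head_lr_mult Learning-rate multiplier for the output weights;
#'   values below 1 keep the sigmoid head's pre-activations out of
#'   saturation on small corpora (see the methods vignette).
#' @param use_attention `FALSE` gives the "no att" ablation: the
#'   projected factor embeddings are fed to the factor encoder directly,
#'   bypassing attention.
#' @param use_labels `FALSE` gives the "no labels" ablation: factor
#'   inputs omit the learned category and time-attribute embeddings.
#' @param seed Integer seed driving initialisation, dropout and
#'   shuffling.
#' @return An `rfab_config` list.
#' @export
rfab_config <- function(embedding_dim = 100L, hidden = 256L, lr = 1e-3,
                        batch_size = 10L, epochs = 60L, dropout = 0.5,
                        decay_rate = 0.99, decay_steps = 500L,
                        warmup_steps = 0L, head_lr_mult = 1,
                        use_attention = TRUE, use_labels = TRUE,
                        seed = 1L) {
  stopifnot(embedding_dim >= 1L, hidden >= 1L, lr > 0, batch_size >= 1L,
            epochs >= 1L, dropout >= 0, dropout < 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 warmup_steps = as.integer(warmup_steps),
                 head_lr_mult = head_lr_mult,
                 use_attention = isTRUE(use_attention),
                 use_labels = isTRUE(use_labels),
                 seed = as.integer(seed)),
            class = "rfab_config")
}

rfab_classes <- function() c("negative", "positive")

init_rfab_params <- function(config, embeddings) {
  stopifnot(config$embedding_dim == embeddings$dim)
  D <- config$embedding_dim
  h <- config$hidden
  char_vocab <- c(colnames(embeddings$vectors), "<OOV>")
  E <- cbind(embeddings$vectors, 0)
  colnames(E) <- char_vocab
  cats <- risk_factor_categories()$code
  atts <- unname(time_attributes())
  cf <- lstm_params(D, h)
  cb <- lstm_params(D, h)
  ff <- lstm_params(2L * h, h)
  fb <- lstm_params(2L * h, h)
  cat_emb <- glorot(D, length(cats)); colnames(cat_emb) <- cats
  attr_emb <- glorot(D, length(atts)); colnames(attr_emb) <- atts
  list(E = E,
       cat_emb = cat_emb, attr_emb = attr_emb,
       no_factor = stats::runif(D, -0.1, 0.1),
       Wcf = cf$W, Ucf = cf$U, bcf = cf$b,
       Wcb = cb$W, Ucb = cb$U, bcb = cb$b,
       proj = glorot(2L * h, D),
       Wff = ff$W, Uff = ff$U, bff = ff$b,
       Wfb = fb$W, Ufb = fb$U, bfb = fb$b,
       Wout = glorot(2L * h, 2L))
}

#' Encode the character context with the first BiLSTM
#'
#' Runs the character-level BiLSTM with zero initial states over the
#' embedded document and returns the per-position outputs
#' `y_t = [h_t_fwd ; h_t_bwd]` together with the final hidden and cell
#' states of both directions, which seed the factor-level BiLSTM.
#'
#' @param EC `m x D` character embedding matrix (row per character).
#' @param params RFAB parameter list (fields `Wcf, Ucf, bcf, Wcb, Ucb,
#'   bcb`).
#' @return List with `Y` (`m x 2h`) and `final` (list `hf, cf, hb, cb`).
#' @export
encode_context <- function(EC, params) {
  if (is.null(dim(EC)) || nrow(EC) < 1L) {
    stop("empty character sequence", call. = FALSE)
  }
  m <- nrow(EC)
  h <- ncol(params$Ucf)
  X <- t(EC)
  z <- numeric(h)
  fw <- cpp_lstm_forward(X, params$Wcf, params$Ucf, params$bcf, z, z)
  bw <- cpp_lstm_forward(X[, m:1, drop = FALSE], params$Wcb, params$Ucb,
                         params$bcb, z, z)
  Y <- t(rbind(fw$H, bw$H[, m:1, drop = FALSE]))
  list(Y = Y,
       final = list(hf = fw$H[, m], cf = fw$C[, m],
                    hb = bw$H[, m], cb = bw$C[, m]),
       fw = fw, bw = bw, X = X)
}

#' Dot-product attention of one risk factor over the character encodings
#'
#' The factor embedding is projected to the encoder's output space
#' (`2h`), dot-products with every character encoding give raw weights,
#' softmax normalises them to `alpha` (non-negative, summing to 1), and
#' the attended vector is the alpha-weighted sum of the character
#' encodings.
#'
#' @param Yc `m x 2h` character encodings.
#' @param ef Factor embedding vector (length D).
#' @param projection `2h x D` projection matrix bridging the factor
#'   embedding into the encoder output space.
#' @return An `attention_record`: list with `weights` (alpha over the m
#'   positions) and `attended` (length-`2h` fused vector).
#' @export
attend <- function(Yc, ef, projection) {
  stopifnot(nrow(Yc) >= 1L)
  q <- as.numeric(projection %*% ef)
  raw <- as.numeric(Yc %*% q)
  a <- exp(raw - max(raw))
  a <- a / sum(a)
  structure(list(weights = a, attended = as.numeric(t(Yc) %*% a), q = q),
            class = "attention_record")
}

#' Encode the attended factor sequence with the second BiLSTM
#'
#' Runs the factor-level BiLSTM over the attended vectors, initialising
#' each direction's hidden and cell state from the character encoder's
#' final states, and returns the final output `Z` (the document
#' representation, length `2h`).
#'
#' @param ET `n x 2h` matrix of attended factor vectors.
#' @param init Final-state list from [encode_context()].
#' @param params RFAB parameter list (fields `Wff, Uff, bff, Wfb, Ufb,
#'   bfb`).
#' @return List with `Z` (length `2h`) and the direction caches.
#' @export
encode_factors <- function(ET, init, params) {
  stopifnot(nrow(ET) >= 1L)
  n <- nrow(ET)
  X <- t(ET)
  fw <- cpp_lstm_forward(X, params$Wff, params$Uff, params$bff,
                         init$hf, init$cf)
  bw <- cpp_lstm_forward(X[, n:1, drop = FALSE], params$Wfb, params$Ufb,
                         params$bfb, init$hb, init$cb)
  list(Z = c(fw$H[, n], bw$H[, n]), fw = fw, bw = bw, X = X)
}

#' Prediction head
#'
#' `O = sigmoid(Z %*% W_out)`, class probabilities `softmax(O)`,
#' predicted label the argmax (which the softmax cannot change).
#'
#' @param Z Document representation vector.
#' @param W_out `length(Z) x K` output weight matrix (K = 2 classes).
#' @return A `prediction_output`: list with `O`, `probabilities` (named
#'   by class), `label`.
#' @export
predict_head <- function(Z, W_out) {
  v <- as.numeric(Z %*% W_out)
  O <- 1 / (1 + exp(-v))
  p <- exp(O - max(O))
  p <- p / sum(p)
  names(p) <- rfab_classes()
  structure(list(O = O, probabilities = p,
                 label = rfab_classes()[which.max(O)], v = v),
            class = "prediction_output")
}

#' @export
print.prediction_output <- function(x, ...) {
  cat(sprintf("<prediction_output> %s (p = %.3f/%.3f)\n", x$label,
              x$probabilities[1], x$probabilities[2]))
  invisible(x)
}

#' Cross-entropy loss of predicted class distributions
#'
#' Mean over documents of `-log p(gold class)`.
#'
#' @param probs List of named probability vectors (or a single one).
#' @param gold Character vector of gold labels.
#' @return Scalar loss.
#' @export
rfab_loss <- function(probs, gold) {
  if (!is.list(probs)) probs <- list(probs)
  stopifnot(length(probs) == length(gold))
  mean(vapply(seq_along(gold), function(i)
    -log(probs[[i]][[gold[i]]]), numeric(1)))
}

#' Build risk-factor input vectors
#'
#' Each mention's base vector is the mean of its surface characters'
#' embeddings; with `use_labels`, learned category and time-attribute
#' embedding vectors are added.  Factors keep document order.  A document
#' with no mentions is represented by the single learned "no-factor"
#' placeholder vector.
#'
#' @param mentions List of [entity_mention()]s (possibly empty).
#' @param params RFAB parameter list.
#' @param use_labels Include the label embeddings?
#' @return List with `EF` (`n x D` matrix), `meta` (data frame with
#'   surface/category/time_attr; zero rows for the placeholder) and
#'   `char_ids` (per factor, the ids of its surface characters; `NULL`
#'   for the placeholder).
#' @export
factor_input <- function(mentions, params, use_labels = TRUE) {
  D <- nrow(params$E)
  char_vocab <- colnames(params$E)
  if (length(mentions) == 0L) {
    return(list(EF = matrix(params$no_factor, nrow = 1L),
                meta = data.frame(surface = character(0),
                                  category = character(0),
                                  time_attr = character(0)),
                char_ids = list(NULL),
                placeholder = TRUE))
  }
  mentions <- mentions[order(vapply(mentions, `[[`, 0L, "start"))]
  cid <- lapply(mentions, function(m)
    char_ids(strsplit(m$surface, "", fixed = TRUE)[[1L]], char_vocab))
  EF <- t(vapply(seq_along(mentions), function(i) {
    v <- rowMeans(params$E[, cid[[i]], drop = FALSE])
    if (use_labels) {
      m <- mentions[[i]]
      v <- v + params$cat_emb[, m$category] + params$attr_emb[, m$time_attr]
    }
    v
  }, numeric(D)))
  list(EF = EF,
       meta = data.frame(
         surface = vapply(mentions, `[[`, "", "surface"),
         category = vapply(mentions, `[[`, "", "category"),
         time_attr = vapply(mentions, `[[`, "", "time_attr"),
         stringsAsFactors = FALSE),
       char_ids = cid,
       placeholder = FALSE)
}

# Full forward pass for one document.  `ids` are character ids into E.
# Dropout (inverted) is applied to the embedding-layer outputs (both the
# character matrix and the factor vectors) when training.
rfab_forward <- function(params, ids, mentions, config, training = FALSE) {
  m <- length(ids)
  h <- config$hidden
  EC <- t(params$E[, ids, drop = FALSE])
  fi <- factor_input(mentions, params, config$use_labels)
  cmask <- fmask <- NULL
  if (training && config$dropout > 0) {
    cmask <- matrix(stats::rbinom(length(EC), 1L, 1 - config$dropout) /
                      (1 - config$dropout), nrow(EC), ncol(EC))
    fmask <- matrix(stats::rbinom(length(fi$EF), 1L, 1 - config$dropout) /
                      (1 - config$dropout), nrow(fi$EF), ncol(fi$EF))
    EC <- EC * cmask
    fi$EF <- fi$EF * fmask
  }
  ctx <- encode_context(EC, params)
  n <- nrow(fi$EF)
  att <- vector("list", n)
  ET <- matrix(0, n, 2L * h)
  for (i in seq_len(n)) {
    if (config$use_attention) {
      att[[i]] <- attend(ctx$Y, fi$EF[i, ], params$proj)
      ET[i, ] <- att[[i]]$attended
    } else {
      q <- as.numeric(params$proj %*% fi$EF[i, ])
      att[[i]] <- structure(list(weights = NULL, attended = q, q = q),
                            class = "attention_record")
      ET[i, ] <- q
    }
  }
  fenc <- encode_factors(ET, ctx$final, params)
  out <- predict_head(fenc$Z, params$Wout)
  list(EC = EC, fi = fi, cmask = cmask, fmask = fmask, ctx = ctx,
       att = att, ET = ET, fenc = fenc, out = out, ids = ids, m = m, n = n)
}

# loss and analytic gradients for one document
rfab_doc_grads <- function(params, ids, mentions, gold, config,
                           training = TRUE) {
  fwd <- rfab_forward(params, ids, mentions, config, training)
  h <- config$hidden
  D <- config$embedding_dim
  m <- fwd$m; n <- fwd$n
  y <- match(gold, rfab_classes())
  loss <- -log(fwd$out$probabilities[[y]])

  # head: softmax(+CE) then sigmoid
  dO <- as.numeric(fwd$out$probabilities)
  dO[y] <- dO[y] - 1
  sig <- fwd$out$O
  dv <- dO * sig * (1 - sig)
  dZ <- as.numeric(params$Wout %*% dv)
  dWout <- outer(fwd$fenc$Z, dv)

  # factor BiLSTM
  z <- numeric(h)
  dHf <- matrix(0, h, n); dHb <- matrix(0, h, n)
  gff <- cpp_lstm_backward(fwd$fenc$X, params$Wff, params$Uff, fwd$fenc$fw$H,
                           fwd$fenc$fw$C, fwd$fenc$fw$G, fwd$ctx$final$hf,
                           fwd$ctx$final$cf, dHf, dZ[1:h], z)
  gfb <- cpp_lstm_backward(fwd$fenc$X[, n:1, drop = FALSE], params$Wfb,
                           params$Ufb, fwd$fenc$bw$H, fwd$fenc$bw$C,
                           fwd$fenc$bw$G, fwd$ctx$final$hb, fwd$ctx$final$cb,
                           dHb, dZ[(h + 1L):(2L * h)], z)
  dET <- t(gff$dX + gfb$dX[, n:1, drop = FALSE])  # n x 2h

  # attention (or direct projection) back to factor embeddings and Yc
  dYc <- matrix(0, m, 2L * h)
  dEF <- matrix(0, n, D)
  dproj <- matrix(0, 2L * h, D)
  for (i in seq_len(n)) {
    det <- dET[i, ]
    if (config$use_attention) {
      a <- fwd$att[[i]]$weights
      q <- fwd$att[[i]]$q
      da <- as.numeric(fwd$ctx$Y %*% det)
      dYc <- dYc + a %o% det
      draw <- a * (da - sum(a * da))
      dq <- as.numeric(t(fwd$ctx$Y) %*% draw)
      dYc <- dYc + draw %o% q
    } else {
      dq <- det
    }
    dproj <- dproj + dq %o% fwd$fi$EF[i, ]
    dEF[i, ] <- as.numeric(t(params$proj) %*% dq)
  }

  # character BiLSTM (upstream: attention on Y, plus the factor encoder's
  # gradient on the final states)
  gcf <- cpp_lstm_backward(fwd$ctx$X, params$Wcf, params$Ucf, fwd$ctx$fw$H,
                           fwd$ctx$fw$C, fwd$ctx$fw$G, z, z,
                           t(dYc[, 1:h, drop = FALSE]), gff$dh0, gff$dc0)
  dYb <- t(dYc[, (h + 1L):(2L * h), drop = FALSE])[, m:1, drop = FALSE]
  gcb <- cpp_lstm_backward(fwd$ctx$X[, m:1, drop = FALSE], params$Wcb,
                           params$Ucb, fwd$ctx$bw$H, fwd$ctx$bw$C,
                           fwd$ctx$bw$G, z, z, dYb, gfb$dh0, gfb$dc0)
  dEC <- t(gcf$dX + gcb$dX[, m:1, drop = FALSE])  # m x D
  if (!is.null(fwd$cmask)) dEC <- dEC * fwd$cmask
  if (!is.null(fwd$fmask)) dEF <- dEF * fwd$fmask

  # embedding-table and label-embedding gradients
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  for (t in seq_len(m)) dE[, ids[t]] <- dE[, ids[t]] + dEC[t, ]
  dcat <- matrix(0, D, ncol(params$cat_emb))
  colnames(dcat) <- colnames(params$cat_emb)
  dattr <- matrix(0, D, ncol(params$attr_emb))
  colnames(dattr) <- colnames(params$attr_emb)
  dno <- numeric(D)
  if (fwd$fi$placeholder) {
    dno <- dno + dEF[1L, ]
  } else {
    for (i in seq_len(n)) {
      cid <- fwd$fi$char_ids[[i]]
      share <- dEF[i, ] / length(cid)
      for (j in cid) dE[, j] <- dE[, j] + share
      if (config$use_labels) {
        cat <- fwd$fi$meta$category[i]
        att <- fwd$fi$meta$time_attr[i]
        dcat[, cat] <- dcat[, cat] + dEF[i, ]
        dattr[, att] <- dattr[, att] + dEF[i, ]
      }
    }
  }
  list(loss = loss, out = fwd$out,
       grads = list(E = dE, cat_emb = dcat, attr_emb = dattr,
                    no_factor = dno,
                    Wcf = gcf$dW, Ucf = gcf$dU, bcf = gcf$db,
                    Wcb = gcb$dW, Ucb = gcb$dU, bcb = gcb$db,
                    proj = dproj,
                    Wff = gff$dW, Uff = gff$dU, bff = gff$db,
                    Wfb = gfb$dW, Ufb = gfb$dU, bfb = gfb$db,
                    Wout = dWout))
}

#' Train the RFAB classifier
#'
#' Adagrad with stepwise learning-rate decay; dropout at the end of the
#' embedding layer; per-epoch development F tracked and the best-dev
#' checkpoint returned.  Factors default to each document's own mentions;
#' supply `train_factors`/`dev_factors` (per-document mention lists, e.g.
#' from [extract_risk_factors()]) to train on tagger output instead.
#'
#' @param train_docs,dev_docs Lists of [emr_document()]s with CVD labels.
#' @param config An [rfab_config()].
#' @param embeddings Pretrained `embedding_table`.
#' @param train_factors,dev_factors Optional per-document mention lists.
#' @param verbose Print per-epoch progress.
#' @return An `rfab_model`: list with `params`, `config`, `history`,
#'   `char_vocab`.
#' @export
train_rfab <- function(train_docs, dev_docs, config, embeddings,
                       train_factors = NULL, dev_factors = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "rfab_config"))
  for (d in c(train_docs, dev_docs)) {
    if (is.null(d$cvd_label)) {
      stop("document '", d$doc_id, "' carries no CVD label", call. = FALSE)
    }
  }
  if (is.null(train_factors)) {
    train_factors <- lapply(train_docs, `[[`, "mentions")
  }
  if (is.null(dev_factors)) {
    dev_factors <- lapply(dev_docs, `[[`, "mentions")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed)
  params <- init_rfab_params(config, embeddings)
  char_vocab <- colnames(params$E)
  ids_list <- lapply(train_docs, function(d) char_ids(d$chars, char_vocab))
  gold <- vapply(train_docs, `[[`, "", "cvd_label")
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
        g <- rfab_doc_grads(params, ids_list[[i]], train_factors[[i]],
                            gold[i], config)
        bl <- bl + g$loss
        acc <- if (is.null(acc)) g$grads else Map(`+`, acc, g$grads)
      }
      nb <- length(batch)
      acc <- lapply(acc, function(x) x / nb)
      lr_t <- decayed_lr(config$lr, config$decay_rate, config$decay_steps,
                         step, config$warmup_steps %||% 0L)
      # the sigmoid-then-softmax head loses its gradient once the output
      # pre-activations saturate; a reduced head learning rate keeps them
      # in the responsive range (see the methods vignette)
      mult <- config$head_lr_mult %||% 1
      if (mult != 1) {
        upd_h <- adagrad_step(params["Wout"], acc["Wout"], state["Wout"],
                              lr_t * mult)
        params$Wout <- upd_h$params$Wout
        state$Wout <- upd_h$state$Wout
        acc$Wout <- NULL
      }
      upd <- adagrad_step(params, acc, state, lr_t)
      params <- upd$params
      state <- upd$state
      step <- step + 1L
      losses <- c(losses, bl / nb)
    }
    model_now <- structure(list(params = params, config = config,
                                char_vocab = char_vocab),
                           class = "rfab_model")
    dev_f <- if (length(dev_docs) > 0L) {
      pred <- vapply(seq_along(dev_docs), function(i)
        predict_rfab(model_now, dev_docs[[i]],
                     dev_factors[[i]])$prediction$label, character(1))
      classification_report(vapply(dev_docs, `[[`, "", "cvd_label"),
                            pred)$F
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         dev_f = dev_f))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  dev F %.2f", ep, mean(losses),
                      dev_f))
    }
    if (!is.na(dev_f) && dev_f > best$f) {
      best <- list(f = dev_f, params = params)
    }
  }
  structure(list(params = if (is.finite(best$f)) best$params else params,
                 config = config, char_vocab = char_vocab,
                 history = history),
            class = "rfab_model")
}

#' @export
print.rfab_model <- function(x, ...) {
  cat("<rfab_model> h = ", x$config$hidden,
      if (!x$config$use_attention) ", no attention" else "",
      if (!x$config$use_labels) ", no labels" else "",
      ", ", nrow(x$history), " epoch(s) trained\n", sep = "")
  invisible(x)
}

#' Predict the CVD label of one document with a trained RFAB model
#'
#' @param model An `rfab_model`.
#' @param doc An [emr_document()].
#' @param factors Mention list to condition on (default: the document's
#'   own mentions).
#' @return List with `prediction` (a `prediction_output`) and
#'   `attention` (list of `attention_record`s with doc/factor metadata;
#'   empty for the no-attention variant).
#' @export
predict_rfab <- function(model, doc, factors = NULL) {
  if (is.null(factors)) factors <- doc$mentions
  if (is.null(factors)) factors <- list()
  ids <- char_ids(doc$chars, model$char_vocab)
  fwd <- rfab_forward(model$params, ids, factors, model$config,
                      training = FALSE)
  recs <- list()
  if (model$config$use_attention) {
    surfs <- if (fwd$fi$placeholder) "<none>" else fwd$fi$meta$surface
    recs <- lapply(seq_len(fwd$n), function(i)
      structure(list(doc_id = doc$doc_id, factor_index = i,
                     surface = surfs[i],
                     weights = fwd$att[[i]]$weights,
                     attended = fwd$att[[i]]$attended),
                class = "attention_record"))
  }
  list(prediction = fwd$out, attention = recs)
}

#' End-to-end prediction: extraction then classification
#'
#' Stage two's tagger extracts the risk factors that stage three's RFAB
#' classifier conditions on, mirroring the full pipeline.
#'
#' @param doc An [emr_document()].
#' @param tagger_model A trained `tagger_model`.
#' @param rfab_model A trained `rfab_model`.
#' @return As [predict_rfab()], plus `factors` (the extracted mentions).
#' @export
predict_document <- function(doc, tagger_model, rfab_model) {
  factors <- extract_risk_factors(doc, tagger_model)
  out <- predict_rfab(rfab_model, doc, factors)
  out$factors <- factors
  out
}

#' Number of trainable parameters of an RFAB configuration
#'
#' Pure function of the configuration and vocabulary sizes (character
#' vocabulary V, 12 categories, 5 attributes, 2 classes).
#'
#' @param config An [rfab_config()].
#' @param n_chars Character vocabulary size V (including the OOV column).
#' @return Integer parameter count.
#' @export
n_rfab_params <- function(config, n_chars) {
  D <- config$embedding_dim
  h <- config$hidden
  lstm <- function(d_in) 4 * h * d_in + 4 * h * h + 4 * h
  D * n_chars +                  # E
    D * 12 + D * 5 + D +         # label embeddings + placeholder
    2 * lstm(D) +                # character BiLSTM
    2 * h * D +                  # projection
    2 * lstm(2 * h) +            # factor BiLSTM
    2 * h * 2                    # output weights
}

#' Save or load an RFAB checkpoint
#'
#' @param model An `rfab_model`.
#' @param path File path.
#' @return `load_rfab()` returns the model; `save_rfab()` the path,
#'   invisibly.
#' @export
save_rfab <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rfab
#' @export
load_rfab <- function(path) readRDS(path)
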