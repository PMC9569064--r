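# Adagrad over a named list of numeric arrays, with stepwise learning-rate
# decay: lr_t = lr * decay_rate ^ floor(step / decay_steps).

adagrad_state <- function(params) {
  lapply(params, function(p) {
    s <- p
    s[] <- 0
    s
  })
}

adagrad_step <- function(params, grads, state, lr, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    # compiled code may hand vectors back as n x 1 matrices
    if (is.null(dim(params[[nm]]))) g <- as.numeric(g)
    state[[nm]] <- state[[nm]] + g * g
    upd <- lr * g / (sqrt(state[[nm]]) + eps)
    # structural -Inf entries (CRF transitions) carry zero gradient; keep
    # them fixed rather than producing -Inf + NaN arithmetic
    p <- params[[nm]]
    fin <- is.finite(p)
    p[fin] <- p[fin] - upd[fin]
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

decayed_lr <- function(lr, decay_rate, decay_steps, step, warmup = 0L) {
  w <- if (warmup > 0L) min(1, (step + 1L) / warmup) else 1
  w * lr * decay_rate^(step %/% decay_steps)
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

# LSTM parameter block for input dimension d_in and hidden size h;
# forget-gate bias initialised to 1
lstm_params <- function(d_in, h) {
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1
  list(W = glorot(4L * h, d_in), U = glorot(4L * h, h), b = b)
}
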