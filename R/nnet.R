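# Native neural-network core: dual-branch unidirectional LSTM with a
# dense funnel and a 2-unit softmax head, trained by mini-batch Adam on
# cross entropy. Implemented over BLAS matrix products; no framework.
#
# Gate layout in the 4u-wide LSTM weight matrices: [input, forget,
# candidate, output]. Biases start at zero except the forget gate at 1
# (the usual stabilising initialisation). PAD timesteps are zero vectors
# processed as ordinary inputs — the gates learn to ignore them.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) (x > 0) * x

glorot <- function(fan_in, fan_out, nrow, ncol) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -l, l), nrow, ncol)
}

lstm_init <- function(d, u) {
  b <- numeric(4L * u)
  b[(u + 1L):(2L * u)] <- 1  # forget-gate bias
  list(W = glorot(d, 4L * u, d, 4L * u),
       U = glorot(u, 4L * u, u, 4L * u),
       b = b)
}

dense_init <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out, n_in, n_out), b = numeric(n_out))
}

# Parameter initialisation for the whole network. `d` embedding dim;
# layer widths from the model config.
nn_init_params <- function(d, units, branch_dense, head_layout) {
  p <- list()
  ctx <- lstm_init(d, units)
  wrd <- lstm_init(d, units)
  p$ctx_W <- ctx$W; p$ctx_U <- ctx$U; p$ctx_b <- ctx$b
  p$wrd_W <- wrd$W; p$wrd_U <- wrd$U; p$wrd_b <- wrd$b
  dc <- dense_init(units, branch_dense)
  dw <- dense_init(units, branch_dense)
  p$dctx_W <- dc$W; p$dctx_b <- dc$b
  p$dwrd_W <- dw$W; p$dwrd_b <- dw$b
  n_in <- 2L * branch_dense
  for (k in seq_along(head_layout)) {
    hk <- dense_init(n_in, head_layout[k])
    p[[paste0("head", k, "_W")]] <- hk$W
    p[[paste0("head", k, "_b")]] <- hk$b
    n_in <- head_layout[k]
  }
  out <- dense_init(n_in, 2L)
  p$out_W <- out$W; p$out_b <- out$b
  p
}

# Run one LSTM over a list of T input matrices (each B x d). Returns the
# final hidden state and, if keep_cache, everything backward needs.
lstm_forward <- function(X, W, U, b, keep_cache = TRUE) {
  B <- nrow(X[[1L]])
  u <- length(b) %/% 4L
  H <- matrix(0, B, u)
  C <- matrix(0, B, u)
  Tn <- length(X)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  bm <- matrix(b, B, 4L * u, byrow = TRUE)
  i1 <- 1L:u; i2 <- (u + 1L):(2L * u)
  i3 <- (2L * u + 1L):(3L * u); i4 <- (3L * u + 1L):(4L * u)
  for (t in seq_len(Tn)) {
    Z <- X[[t]] %*% W + H %*% U + bm
    ig <- sigmoid(Z[, i1, drop = FALSE])
    fg <- sigmoid(Z[, i2, drop = FALSE])
    gg <- tanh(Z[, i3, drop = FALSE])
    og <- sigmoid(Z[, i4, drop = FALSE])
    C_new <- fg * C + ig * gg
    tc <- tanh(C_new)
    H_new <- og * tc
    if (keep_cache) {
      cache[[t]] <- list(i = ig, f = fg, g = gg, o = og, tc = tc,
                         c_prev = C, h_prev = H, x = X[[t]])
    }
    C <- C_new
    H <- H_new
  }
  list(H = H, cache = cache)
}

# Backpropagation through time, given the gradient at the final hidden
# state. Input gradients are not needed (embeddings are fixed).
lstm_backward <- function(dH, cache, W, U) {
  Tn <- length(cache)
  u <- ncol(dH)
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, u, 4L * u)
  db <- numeric(4L * u)
  dC <- matrix(0, nrow(dH), u)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dO <- dH * cc$tc
    dC <- dC + dH * cc$o * (1 - cc$tc^2)
    dI <- dC * cc$g
    dF <- dC * cc$c_prev
    dG <- dC * cc$i
    dZ <- cbind(dI * cc$i * (1 - cc$i),
                dF * cc$f * (1 - cc$f),
                dG * (1 - cc$g^2),
                dO * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dZ)
    dU <- dU + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dH <- tcrossprod(dZ, U)
    dC <- dC * cc$f
  }
  list(W = dW, U = dU, b = db)
}

add_bias <- function(Z, b) sweep(Z, 2L, b, `+`)

# Full forward pass. Xctx: list of 2n B x d matrices; Xwrd: B x d.
nn_forward <- function(p, Xctx, Xwrd, keep_cache = TRUE) {
  ctx <- lstm_forward(Xctx, p$ctx_W, p$ctx_U, p$ctx_b, keep_cache)
  wrd <- lstm_forward(list(Xwrd), p$wrd_W, p$wrd_U, p$wrd_b, keep_cache)
  Dc <- relu(add_bias(ctx$H %*% p$dctx_W, p$dctx_b))
  Dw <- relu(add_bias(wrd$H %*% p$dwrd_W, p$dwrd_b))
  A <- cbind(Dc, Dw)
  n_head <- sum(grepl("^head[0-9]+_W$", names(p)))
  head_acts <- vector("list", n_head)
  for (k in seq_len(n_head)) {
    A <- relu(add_bias(A %*% p[[paste0("head", k, "_W")]],
                       p[[paste0("head", k, "_b")]]))
    head_acts[[k]] <- A
  }
  logits <- add_bias(A %*% p$out_W, p$out_b)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  P <- e / rowSums(e)
  out <- list(P = P)
  if (keep_cache) {
    out$cache <- list(ctx = ctx, wrd = wrd, Dc = Dc, Dw = Dw,
                      head_acts = head_acts, n_head = n_head)
  }
  out
}

# Cross entropy over one-hot 2-class targets (the "binary cross
# entropy" of a 2-unit softmax head) and classification accuracy.
nn_loss_acc <- function(P, y) {
  eps <- 1e-12
  picked <- P[cbind(seq_along(y), y + 1L)]
  list(loss = -mean(log(pmax(picked, eps))),
       acc = mean((P[, 2L] >= P[, 1L]) == (y == 1L)))
}

nn_backward <- function(p, fwd, Xctx, Xwrd, y) {
  B <- length(y)
  cache <- fwd$cache
  g <- list()
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dlog <- (fwd$P - Y) / B
  A_last <- if (cache$n_head) cache$head_acts[[cache$n_head]] else
    cbind(cache$Dc, cache$Dw)
  g$out_W <- crossprod(A_last, dlog)
  g$out_b <- colSums(dlog)
  dA <- tcrossprod(dlog, p$out_W)
  for (k in rev(seq_len(cache$n_head))) {
    Ak <- cache$head_acts[[k]]
    dA <- dA * (Ak > 0)
    A_in <- if (k > 1L) cache$head_acts[[k - 1L]] else
      cbind(cache$Dc, cache$Dw)
    g[[paste0("head", k, "_W")]] <- crossprod(A_in, dA)
    g[[paste0("head", k, "_b")]] <- colSums(dA)
    dA <- tcrossprod(dA, p[[paste0("head", k, "_W")]])
  }
  bd <- ncol(cache$Dc)
  dDc <- dA[, seq_len(bd), drop = FALSE] * (cache$Dc > 0)
  dDw <- dA[, bd + seq_len(bd), drop = FALSE] * (cache$Dw > 0)
  g$dctx_W <- crossprod(cache$ctx$H, dDc)
  g$dctx_b <- colSums(dDc)
  g$dwrd_W <- crossprod(cache$wrd$H, dDw)
  g$dwrd_b <- colSums(dDw)
  dHc <- tcrossprod(dDc, p$dctx_W)
  dHw <- tcrossprod(dDw, p$dwrd_W)
  gc_ <- lstm_backward(dHc, cache$ctx$cache, p$ctx_W, p$ctx_U)
  gw_ <- lstm_backward(dHw, cache$wrd$cache, p$wrd_W, p$wrd_U)
  g$ctx_W <- gc_$W; g$ctx_U <- gc_$U; g$ctx_b <- gc_$b
  g$wrd_W <- gw_$W; g$wrd_U <- gw_$U; g$wrd_b <- gw_$b
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Slice a (N, T, d) context array + (N, d) word matrix into the batch
# form nn_forward expects.
nn_batch_inputs <- function(examples, idx) {
  d <- examples$d
  Tn <- dim(examples$context)[2L]
  ctx <- lapply(seq_len(Tn), function(t) {
    m <- examples$context[idx, t, , drop = FALSE]
    dim(m) <- c(length(idx), d)
    m
  })
  wrd <- examples$word[idx, , drop = FALSE]
  list(ctx = ctx, wrd = wrd)
}

# Forward-only evaluation in chunks; returns P (N x 2).
nn_predict_proba <- function(params, examples, chunk = 512L) {
  N <- length(examples$label)
  P <- matrix(NA_real_, N, 2L)
  at <- 1L
  while (at <= N) {
    idx <- at:min(N, at + chunk - 1L)
    b <- nn_batch_inputs(examples, idx)
    P[idx, ] <- nn_forward(params, b$ctx, b$wrd, keep_cache = FALSE)$P
    at <- at + chunk
  }
  P
}
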