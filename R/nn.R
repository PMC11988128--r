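# Recurrent / attention / convolution primitives with hand-written backward
# passes. Sequences are lists over time of B x d matrices (B parallel
# sequences, right-padded); masks are B x T. Masked steps are pass-throughs:
# the recurrent state carries unchanged, so appending padding never perturbs
# outputs at valid positions (exact padding invariance). All gradients are
# verified against central finite differences in the test suite.

gate_cols <- function(h) {
  list(i = seq_len(h), f = h + seq_len(h), o = 2L * h + seq_len(h),
       g = 3L * h + seq_len(h))
}

lstm_forward <- function(X, M, p) {
  Tn <- length(X)
  B <- nrow(M)
  h <- nrow(p$Wh)
  gc <- gate_cols(h)
  Hprev <- matrix(0, B, h)
  Cprev <- matrix(0, B, h)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    m <- as.numeric(M[, t])
    A <- X[[t]] %*% p$Wx + Hprev %*% p$Wh
    A <- A + rep(p$b, each = B)
    gi <- sigmoid(A[, gc$i, drop = FALSE])
    gf <- sigmoid(A[, gc$f, drop = FALSE])
    go <- sigmoid(A[, gc$o, drop = FALSE])
    gg <- tanh(A[, gc$g, drop = FALSE])
    Cnew <- gf * Cprev + gi * gg
    tc <- tanh(Cnew)
    Hnew <- go * tc
    Hcur <- m * Hnew + (1 - m) * Hprev
    Ccur <- m * Cnew + (1 - m) * Cprev
    cache[[t]] <- list(X = X[[t]], Hprev = Hprev, Cprev = Cprev,
                       i = gi, f = gf, o = go, g = gg, tc = tc, m = m)
    H[[t]] <- Hcur
    Hprev <- Hcur
    Cprev <- Ccur
  }
  list(H = H, cache = cache)
}

lstm_backward <- function(dH, fwd, p) {
  Tn <- length(dH)
  B <- nrow(dH[[1]])
  h <- nrow(p$Wh)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    m <- cc$m
    dh <- dH[[t]] + dh_next
    dh_cell <- dh * m
    dh_carry <- dh * (1 - m)
    dc_carry <- dc_next * (1 - m)
    dc <- dc_next * m + dh_cell * cc$o * (1 - cc$tc^2)
    d_o <- dh_cell * cc$tc
    d_i <- dc * cc$g
    d_g <- dc * cc$i
    d_f <- dc * cc$Cprev
    dA <- cbind(d_i * cc$i * (1 - cc$i),
                d_f * cc$f * (1 - cc$f),
                d_o * cc$o * (1 - cc$o),
                d_g * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$X, dA)
    dWh <- dWh + crossprod(cc$Hprev, dA)
    db <- db + colSums(dA)
    dX[[t]] <- dA %*% t(p$Wx)
    dh_next <- dA %*% t(p$Wh) + dh_carry
    dc_next <- dc * cc$f + dc_carry
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# Bidirectional wrapper; forward and backward states are concatenated
# (forward || backward) at each position.
bilstm_forward <- function(X, M, p) {
  Tn <- length(X)
  f <- lstm_forward(X, M, p$fwd)
  b <- lstm_forward(X[rev(seq_len(Tn))], M[, rev(seq_len(Tn)), drop = FALSE],
                    p$bwd)
  Hb <- b$H[rev(seq_len(Tn))]
  H <- lapply(seq_len(Tn), function(t) cbind(f$H[[t]], Hb[[t]]))
  list(H = H, f = f, b = b)
}

bilstm_backward <- function(dH, fb, p) {
  Tn <- length(dH)
  h <- nrow(p$fwd$Wh)
  dHf <- lapply(dH, function(d) d[, seq_len(h), drop = FALSE])
  dHb <- lapply(dH, function(d) d[, h + seq_len(h), drop = FALSE])
  rf <- lstm_backward(dHf, fb$f, p$fwd)
  rb <- lstm_backward(dHb[rev(seq_len(Tn))], fb$b, p$bwd)
  dXb <- rb$dX[rev(seq_len(Tn))]
  dX <- lapply(seq_len(Tn), function(t) rf$dX[[t]] + dXb[[t]])
  list(dX = dX, grads = list(fwd = rf$grads, bwd = rb$grads))
}

# Additive attention in the hierarchical-attention-network formulation:
# u_t = tanh(W h_t + b), scores u_t . v, softmax over unmasked positions,
# context = sum_t alpha_t h_t.
attn_forward <- function(H, M, p) {
  Tn <- length(H)
  B <- nrow(M)
  if (any(rowSums(M) == 0)) stop_config("attention over an all-masked sequence")
  U <- vector("list", Tn)
  S <- matrix(-Inf, B, Tn)
  for (t in seq_len(Tn)) {
    U[[t]] <- tanh(H[[t]] %*% p$Wa + rep(p$ba, each = B))
    S[, t] <- U[[t]] %*% p$v
  }
  S[!M] <- -Inf
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E[!M] <- 0
  alpha <- E / rowSums(E)
  ctx <- matrix(0, B, ncol(H[[1]]))
  for (t in seq_len(Tn)) ctx <- ctx + alpha[, t] * H[[t]]
  list(ctx = ctx, alpha = alpha, U = U)
}

attn_backward <- function(dctx, fwd, H, M, p) {
  Tn <- length(H)
  B <- nrow(M)
  alpha <- fwd$alpha
  dalpha <- matrix(0, B, Tn)
  dH <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- rowSums(dctx * H[[t]])
    dH[[t]] <- alpha[, t] * dctx
  }
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  dS[!M] <- 0
  dWa <- matrix(0, nrow(p$Wa), ncol(p$Wa))
  dba <- numeric(length(p$ba))
  dv <- numeric(length(p$v))
  for (t in seq_len(Tn)) {
    u <- fwd$U[[t]]
    ds <- dS[, t]
    dv <- dv + colSums(u * ds)
    dpre <- tcrossprod(ds, p$v) * (1 - u^2)
    dWa <- dWa + crossprod(H[[t]], dpre)
    dba <- dba + colSums(dpre)
    dH[[t]] <- dH[[t]] + dpre %*% t(p$Wa)
  }
  list(dH = dH, grads = list(Wa = dWa, ba = dba, v = dv))
}

# Masked mean pooling (the hierarchy-without-attention variant): uniform
# weights 1/len over unmasked positions.
meanpool_forward <- function(H, M) {
  Tn <- length(H)
  B <- nrow(M)
  len <- rowSums(M)
  if (any(len == 0)) stop_config("mean pooling over an all-masked sequence")
  ctx <- matrix(0, B, ncol(H[[1]]))
  for (t in seq_len(Tn)) ctx <- ctx + as.numeric(M[, t]) * H[[t]]
  ctx <- ctx / len
  alpha <- M / len
  list(ctx = ctx, alpha = alpha)
}

meanpool_backward <- function(dctx, M) {
  len <- rowSums(M)
  lapply(seq_len(ncol(M)), function(t) (as.numeric(M[, t]) / len) * dctx)
}

# 1-D convolution over a word sequence via unfolding: row t of the unfolded
# matrix is the zero-padded window [x_{t-r}, ..., x_{t+r}] (same padding).
unfold_seq <- function(X, k) {
  Tn <- nrow(X)
  d <- ncol(X)
  r <- (k - 1L) %/% 2L
  out <- matrix(0, Tn, k * d)
  for (s in seq_len(k)) {
    shift <- s - 1L - r
    src <- seq_len(Tn) + shift
    ok <- src >= 1L & src <= Tn
    out[ok, (s - 1L) * d + seq_len(d)] <- X[src[ok], , drop = FALSE]
  }
  out
}

fold_seq_grad <- function(dU, k, d, Tn) {
  r <- (k - 1L) %/% 2L
  dX <- matrix(0, Tn, d)
  for (s in seq_len(k)) {
    shift <- s - 1L - r
    src <- seq_len(Tn) + shift
    ok <- src >= 1L & src <= Tn
    dX[src[ok], ] <- dX[src[ok], , drop = FALSE] +
      dU[ok, (s - 1L) * d + seq_len(d), drop = FALSE]
  }
  dX
}

# Column-wise max over a row range with argmax bookkeeping for backprop.
maxpool_rows <- function(X, rows) {
  sub <- X[rows, , drop = FALSE]
  at <- max.col(t(sub), ties.method = "first")
  list(v = sub[cbind(at, seq_len(ncol(sub)))], arg = rows[at])
}

# ---- parameter initialisation -------------------------------------------

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_lstm <- function(d, h) {
  b <- numeric(4L * h)
  b[h + seq_len(h)] <- 1 # forget-gate bias, standard recurrent initialisation
  list(Wx = glorot(d, 4L * h), Wh = glorot(h, 4L * h), b = b)
}

init_bilstm <- function(d, h) list(fwd = init_lstm(d, h), bwd = init_lstm(d, h))

init_attn <- function(D, a) {
  list(Wa = glorot(D, a), ba = numeric(a),
       v = stats::runif(a, -sqrt(3 / a), sqrt(3 / a)))
}

init_head <- function(q) list(w = stats::runif(q, -sqrt(3 / q), sqrt(3 / q)), b = 0)

init_dense <- function(p, q) list(W = glorot(p, q), b = numeric(q))
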