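# Low-level neural-network primitives: forward and backward passes for
# embeddings, masked bidirectional LSTM layers, layer normalization,
# multi-head self-attention, linear layers, ReLU and inverted dropout.
# Weights follow the (out_features x in_features) convention; activations are
# (batch, length, dim) arrays. All padded positions are controlled by an
# explicit validity mask so no loss component and no attention weight ever
# touches padding. Backward passes are verified against central finite
# differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# (B, L, D) array -> (B*L, D) matrix view and back
.mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}
.arr3 <- function(x, B, L) {
  dim(x) <- c(B, L, ncol(x))
  x
}
.sliceT <- function(x, t) matrix(x[, t, ], nrow = dim(x)[1])

# ---- initializers ------------------------------------------------------

.initUniform <- function(nr, nc, bound, rng_env) {
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

.xavierUniform <- function(nr, nc, gain = 1) {
  # nr = fan_out, nc = fan_in
  bound <- gain * sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

.linearDefault <- function(out_dim, in_dim) {
  bound <- 1 / sqrt(in_dim)
  list(W = matrix(runif(out_dim * in_dim, -bound, bound), out_dim, in_dim),
       b = runif(out_dim, -bound, bound))
}

# ---- linear ------------------------------------------------------------

.linearForward <- function(x, W, b) {
  B <- dim(x)[1]; L <- dim(x)[2]
  y <- .mat3(x) %*% t(W)
  y <- y + matrix(b, nrow(y), length(b), byrow = TRUE)
  .arr3(y, B, L)
}

# returns list(dx, dW, db); x is the forward input
.linearBackward <- function(dy, x, W) {
  B <- dim(x)[1]; L <- dim(x)[2]
  dyM <- .mat3(dy); xM <- .mat3(x)
  list(dx = .arr3(dyM %*% W, B, L),
       dW = t(dyM) %*% xM,
       db = colSums(dyM))
}

# ---- embedding ---------------------------------------------------------

# tokens: (B, L) 0-based integer matrix (pad id = nrow(E) - 1)
.embedForward <- function(tokens, E) {
  B <- nrow(tokens); L <- ncol(tokens)
  out <- E[as.vector(tokens) + 1L, , drop = FALSE]
  .arr3(out, B, L)
}

.embedBackward <- function(dy, tokens, n_rows) {
  dE <- matrix(0, n_rows, dim(dy)[3])
  dyM <- .mat3(dy)
  idx <- as.vector(tokens) + 1L
  for (r in unique(idx)) {
    rows <- which(idx == r)
    dE[r, ] <- colSums(dyM[rows, , drop = FALSE])
  }
  dE
}

# ---- masked LSTM (one direction) --------------------------------------

# x: (B, L, in); mask: (B, L) logical; reverse: run right-to-left.
# Weights: W_ih (4H x in), W_hh (4H x H), b_ih, b_hh (4H). Gate order
# i, f, g, o. Masked steps carry h and c through unchanged, so padding on
# either end never leaks into real positions.
.lstmForward <- function(x, mask, W_ih, W_hh, b_ih, b_hh, reverse = FALSE,
                         keep_cache = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]
  H <- length(b_ih) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, dim = c(B, L, H))
  cache <- if (keep_cache) vector("list", L) else NULL
  b <- b_ih + b_hh
  ts <- if (reverse) L:1 else 1:L
  for (t in ts) {
    xt <- .sliceT(x, t)
    m <- mask[, t]
    g <- xt %*% t(W_ih) + h %*% t(W_hh)
    g <- g + matrix(b, B, 4L * H, byrow = TRUE)
    i_g <- .sigmoid(g[, 1:H, drop = FALSE])
    f_g <- .sigmoid(g[, (H + 1):(2 * H), drop = FALSE])
    g_g <- tanh(g[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- .sigmoid(g[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i_g, f = f_g,
                         g = g_g, o = o_g, tc = tc, m = m)
    mm <- matrix(m, B, H)
    cc <- ifelse(mm, c_new, cc)
    h <- ifelse(mm, h_new, h)
    out[, t, ] <- h
  }
  list(out = out, cache = cache)
}

.lstmBackward <- function(dout, x, mask, W_ih, W_hh, cache, reverse = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]
  H <- ncol(W_hh)
  dW_ih <- matrix(0, nrow(W_ih), ncol(W_ih))
  dW_hh <- matrix(0, 4L * H, H)
  db <- numeric(4L * H)
  dx <- array(0, dim = dim(x))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  ts <- if (reverse) 1:L else L:1   # reverse of forward order
  for (t in ts) {
    cc <- cache[[t]]
    mm <- matrix(cc$m, B, H)
    dh_t <- dh + .sliceT(dout, t)
    dh_new <- ifelse(mm, dh_t, 0)
    dh_pass <- ifelse(mm, 0, dh_t)
    dc_new <- ifelse(mm, dc, 0)
    dc_pass <- ifelse(mm, 0, dc)
    do_g <- dh_new * cc$tc
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tc^2)
    df_g <- dc_new * cc$c_prev
    di_g <- dc_new * cc$g
    dg_g <- dc_new * cc$i
    dc_prev <- dc_new * cc$f + dc_pass
    dgate <- cbind(di_g * cc$i * (1 - cc$i),
                   df_g * cc$f * (1 - cc$f),
                   dg_g * (1 - cc$g^2),
                   do_g * cc$o * (1 - cc$o))
    dW_ih <- dW_ih + t(dgate) %*% cc$xt
    dW_hh <- dW_hh + t(dgate) %*% cc$h_prev
    db <- db + colSums(dgate)
    dx[, t, ] <- dgate %*% W_ih
    dh <- dgate %*% W_hh + dh_pass
    dc <- dc_prev
  }
  list(dx = dx, dW_ih = dW_ih, dW_hh = dW_hh, db_ih = db, db_hh = db)
}

# ---- layer normalization ----------------------------------------------

.layerNormForward <- function(x, gamma, beta, eps = 1e-5, keep_cache = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]; D <- dim(x)[3]
  xM <- .mat3(x)
  mu <- rowMeans(xM)
  xc <- xM - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * matrix(gamma, nrow(xM), D, byrow = TRUE) +
    matrix(beta, nrow(xM), D, byrow = TRUE)
  list(out = .arr3(y, B, L),
       cache = if (keep_cache) list(xhat = xhat, inv = inv, D = D) else NULL)
}

.layerNormBackward <- function(dy, gamma, cache) {
  B <- dim(dy)[1]; L <- dim(dy)[2]; D <- dim(dy)[3]
  dyM <- .mat3(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dyM * xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * matrix(gamma, nrow(dyM), D, byrow = TRUE)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = .arr3(dx, B, L), dgamma = dgamma, dbeta = dbeta)
}

# ---- multi-head self-attention ----------------------------------------

# Packed in-projection (3E x E) producing Q, K, V; padded keys are excluded
# by setting their scores to -Inf before the softmax.
.attentionForward <- function(x, mask, W_in, b_in, W_out, b_out, n_heads,
                              keep_cache = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]; E <- dim(x)[3]
  dh <- E %/% n_heads
  qkv <- .linearForward(x, W_in, b_in)   # (B, L, 3E)
  O <- array(0, dim = c(B, L, E))
  A_cache <- if (keep_cache) vector("list", B) else NULL
  for (b in seq_len(B)) {
    Qb <- matrix(qkv[b, , 1:E], L, E)
    Kb <- matrix(qkv[b, , (E + 1):(2 * E)], L, E)
    Vb <- matrix(qkv[b, , (2 * E + 1):(3 * E)], L, E)
    keyok <- mask[b, ]
    Ab <- if (keep_cache) vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- (Qb[, cols, drop = FALSE] %*% t(Kb[, cols, drop = FALSE])) / sqrt(dh)
      S[, !keyok] <- -Inf
      S <- S - apply(S, 1, max)
      eS <- exp(S)
      A <- eS / rowSums(eS)
      O[b, , cols] <- A %*% Vb[, cols, drop = FALSE]
      if (keep_cache) Ab[[h]] <- A
    }
    if (keep_cache) A_cache[[b]] <- Ab
  }
  out <- .linearForward(O, W_out, b_out)
  list(out = out,
       cache = if (keep_cache) list(qkv = qkv, O = O, A = A_cache) else NULL)
}

.attentionBackward <- function(dy, x, mask, W_in, W_out, n_heads, cache) {
  B <- dim(x)[1]; L <- dim(x)[2]; E <- dim(x)[3]
  dh <- E %/% n_heads
  outb <- .linearBackward(dy, cache$O, W_out)
  dO <- outb$dx
  dqkv <- array(0, dim = c(B, L, 3 * E))
  for (b in seq_len(B)) {
    Qb <- matrix(cache$qkv[b, , 1:E], L, E)
    Kb <- matrix(cache$qkv[b, , (E + 1):(2 * E)], L, E)
    Vb <- matrix(cache$qkv[b, , (2 * E + 1):(3 * E)], L, E)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- cache$A[[b]][[h]]
      dOb <- matrix(dO[b, , cols], L, dh)
      dV <- t(A) %*% dOb
      dA <- dOb %*% t(Vb[, cols, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ <- (dS %*% Kb[, cols, drop = FALSE]) / sqrt(dh)
      dK <- (t(dS) %*% Qb[, cols, drop = FALSE]) / sqrt(dh)
      dqkv[b, , cols] <- dQ
      dqkv[b, , E + cols] <- dK
      dqkv[b, , 2 * E + cols] <- dV
    }
  }
  inb <- .linearBackward(dqkv, x, W_in)
  list(dx = inb$dx, dW_in = inb$dW, db_in = inb$db,
       dW_out = outb$dW, db_out = outb$db)
}

# ---- dropout -----------------------------------------------------------

.dropoutMask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}
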