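# Low-level neural network primitives (forward + backward) in base R.
# Activations travel as 3-D arrays dim = c(batch, length, channels); reshaping
# between array and (batch*length) x channels matrix is a zero-copy dim change
# in column-major layout.

# Sigmoid-parameterized GELU (x * sigmoid(1.702 x)); the gate is cached in
# the forward pass so the backward pass needs no transcendental calls.
GELU <- function(x) x / (1 + exp(-1.702 * x))

gelu_forward <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  list(out = x * s, s = s)
}

gelu_grad_cached <- function(x, s) s * (1 + 1.702 * x * (1 - s))

gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  gelu_grad_cached(x, s)
}

# Numerically stable row-wise softmax of a matrix.
softmax_rows <- function(m) {
  if (ncol(m) == 1L) return(matrix(1, nrow(m), 1L))
  rmax <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - rmax)
  e / rowSums(e)
}

as_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

as_arr <- function(m, B, L) {
  dim(m) <- c(B, L, ncol(m))
  m
}

# --- 1-D convolution, stride 1, zero "same" padding ---------------------------
# A: (B, P, Cin); W: (kernel*Cin, Cout) with kernel-offset-major blocks;
# b: length Cout. In the flattened (B*P, C) layout a position shift of s is a
# row shift of s*B, so the convolution is a sum of `kernel` shifted row-block
# GEMMs -- no im2col buffer is materialized.

conv1d_forward <- function(A, W, b, kernel) {
  d <- dim(A); B <- d[1]; P <- d[2]; Cin <- d[3]
  half <- (kernel - 1L) %/% 2L
  Am <- as_mat(A)
  Cout <- ncol(W)
  Y <- matrix(b, B * P, Cout, byrow = TRUE)
  for (o in seq_len(kernel)) {
    s <- o - half - 1L  # input offset for this kernel tap
    p_lo <- max(1L, 1L - s); p_hi <- min(P, P - s)
    if (p_lo > p_hi) next
    rows_out <- ((p_lo - 1L) * B + 1L):(p_hi * B)
    Wb <- W[((o - 1L) * Cin + 1L):(o * Cin), , drop = FALSE]
    Y[rows_out, ] <- Y[rows_out, , drop = FALSE] +
      Am[rows_out + s * B, , drop = FALSE] %*% Wb
  }
  list(out = as_arr(Y, B, P))
}

# `A` is the stage input (cached by the caller).
conv1d_backward <- function(dY, A, W, kernel, Cin) {
  d <- dim(dY); B <- d[1]; P <- d[2]
  dYm <- as_mat(dY)
  Am <- as_mat(A)
  half <- (kernel - 1L) %/% 2L
  dW <- matrix(0, nrow(W), ncol(W))
  dAm <- matrix(0, nrow(Am), Cin)
  for (o in seq_len(kernel)) {
    s <- o - half - 1L
    p_lo <- max(1L, 1L - s); p_hi <- min(P, P - s)
    if (p_lo > p_hi) next
    rows_out <- ((p_lo - 1L) * B + 1L):(p_hi * B)
    rows_in <- rows_out + s * B
    wrows <- ((o - 1L) * Cin + 1L):(o * Cin)
    dW[wrows, ] <- crossprod(Am[rows_in, , drop = FALSE], dYm[rows_out, , drop = FALSE])
    dAm[rows_in, ] <- dAm[rows_in, , drop = FALSE] +
      dYm[rows_out, , drop = FALSE] %*% t(W[wrows, , drop = FALSE])
  }
  list(dA = as_arr(dAm, B, P), dW = dW, db = colSums(dYm))
}

# --- non-overlapping max pooling along the position axis ----------------------
# Pads the tail with -Inf when P is not a multiple of `pool`.

maxpool_forward <- function(A, pool) {
  d <- dim(A); B <- d[1]; P <- d[2]; C <- d[3]
  L <- ceiling(P / pool)
  if (P < L * pool) {
    Ap <- array(-Inf, c(B, L * pool, C))
    Ap[, seq_len(P), ] <- A
    A <- Ap
  }
  out <- A[, seq(1L, L * pool, by = pool), , drop = FALSE]
  arg <- array(1L, dim(out))
  if (pool > 1) for (w in 2:pool) {
    Sw <- A[, seq(w, L * pool, by = pool), , drop = FALSE]
    m <- Sw > out
    out[m] <- Sw[m]
    arg[m] <- w
  }
  list(out = out, arg = arg, P = P, pool = pool)
}

maxpool_backward <- function(dOut, cache) {
  d <- dim(dOut); B <- d[1]; L <- d[2]; C <- d[3]
  pool <- cache$pool
  dA <- array(0, c(B, L * pool, C))
  for (w in seq_len(pool)) {
    m <- cache$arg == w
    slice <- array(0, d)
    slice[m] <- dOut[m]
    dA[, seq(w, L * pool, by = pool), ] <- slice
  }
  dA[, seq_len(cache$P), , drop = FALSE]
}

# --- layer normalization over the feature axis --------------------------------
# X: (N, d) matrix; g, b: length-d scale/shift.

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, "*")
  Y <- sweep(Y, 2, b, "+")
  list(out = Y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# --- multi-head scaled dot-product self-attention -----------------------------
# X: (B, L, d) array. Weight matrices d x d, bias length d. Attention
# matrices are cached per sample and head for the backward pass and for
# interpretability.

mha_forward <- function(X, p, n_heads) {
  d3 <- dim(X); B <- d3[1]; L <- d3[2]; dd <- d3[3]
  dh <- dd %/% n_heads
  Xm <- as_mat(X)
  Q <- as_arr(sweep(Xm %*% p$Wq, 2, p$bq, "+"), B, L)
  K <- as_arr(sweep(Xm %*% p$Wk, 2, p$bk, "+"), B, L)
  V <- as_arr(sweep(Xm %*% p$Wv, 2, p$bv, "+"), B, L)
  O <- array(0, c(B, L, dd))
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    Qb <- matrix(Q[b, , ], L, dd); Kb <- matrix(K[b, , ], L, dd); Vb <- matrix(V[b, , ], L, dd)
    Ab <- vector("list", n_heads)
    Ob <- matrix(0, L, dd)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Qb[, idx, drop = FALSE], Kb[, idx, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      Ob[, idx] <- A %*% Vb[, idx, drop = FALSE]
      Ab[[h]] <- A
    }
    O[b, , ] <- Ob
    attn[[b]] <- Ab
  }
  out <- sweep(as_mat(O) %*% p$Wo, 2, p$bo, "+")
  list(out = as_arr(out, B, L), cache = list(X = Xm, Q = Q, K = K, V = V, O = O,
                                             attn = attn, B = B, L = L, dh = dh))
}

mha_backward <- function(dOut, p, cache, n_heads) {
  B <- cache$B; L <- cache$L; dh <- cache$dh
  dd <- dh * n_heads
  dOm <- as_mat(dOut)
  dWo <- crossprod(as_mat(cache$O), dOm)
  dbo <- colSums(dOm)
  dO <- as_arr(dOm %*% t(p$Wo), B, L)
  dQ <- array(0, c(B, L, dd)); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    dOb <- matrix(dO[b, , ], L, dd)
    Qb <- matrix(cache$Q[b, , ], L, dd); Kb <- matrix(cache$K[b, , ], L, dd)
    Vb <- matrix(cache$V[b, , ], L, dd)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$attn[[b]][[h]]
      dA <- tcrossprod(dOb[, idx, drop = FALSE], Vb[, idx, drop = FALSE])
      dV[b, , idx] <- crossprod(A, dOb[, idx, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[b, , idx] <- dS %*% Kb[, idx, drop = FALSE] / sqrt(dh)
      dK[b, , idx] <- crossprod(dS, Qb[, idx, drop = FALSE]) / sqrt(dh)
    }
  }
  dQm <- as_mat(dQ); dKm <- as_mat(dK); dVm <- as_mat(dV)
  dX <- dQm %*% t(p$Wq) + dKm %*% t(p$Wk) + dVm %*% t(p$Wv)
  list(
    dX = dX,
    grads = list(Wq = crossprod(cache$X, dQm), bq = colSums(dQm),
                 Wk = crossprod(cache$X, dKm), bk = colSums(dKm),
                 Wv = crossprod(cache$X, dVm), bv = colSums(dVm),
                 Wo = dWo, bo = dbo)
  )
}

# --- dropout (inverted scaling; identity in eval mode) ------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array(stats::runif(length(X)) >= rate, dim = dim(X) %||% length(X))
  list(out = X * mask / (1 - rate), mask = mask, rate = rate)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) return(dY)
  dY * cache$mask / (1 - cache$rate)
}

# --- fixed sinusoidal positional encodings over the token index ---------------

positional_encoding <- function(L, d) {
  pe <- matrix(0, L, d)
  pos <- seq_len(L) - 1L
  for (j in seq_len(ceiling(d / 2))) {
    freq <- 1 / (10000^((2 * (j - 1)) / d))
    pe[, 2 * j - 1] <- sin(pos * freq)
    if (2 * j <= d) pe[, 2 * j] <- cos(pos * freq)
  }
  pe
}
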