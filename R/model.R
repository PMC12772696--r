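# Architecture: CpG-wise linear projection -> 1-D convolutional tokenizer
# (GELU + max pooling, sinusoidal positional encodings) -> pre-norm
# transformer backbone (final block keeps its attention maps) -> mean pooling
# fused with covariate and tissue embeddings -> softmax classifier.
#
# The projection is depthwise (one weight and bias per CpG): output site p
# depends only on input site p, so the weights read like per-site regression
# coefficients. Tissue identity enters only at the classifier head, so
# attention maps are tissue-independent by construction.

#' Architecture specification
#'
#' @param P Number of input CpG sites.
#' @param n_tissues Number of tissue codes R (embedding rows).
#' @param n_classes Number of diagnostic classes C.
#' @param conv_channels Channel widths of the convolution stages; the last
#'   entry is the token width `d`.
#' @param conv_kernel Odd convolution kernel width (stride 1, zero-padded).
#' @param pools Max-pooling widths, one per convolution stage; the token count
#'   is `L = ceiling(P / prod(pools))` and must satisfy `L <= P/4`.
#' @param n_layers Transformer depth.
#' @param n_heads Attention heads (must divide `d`).
#' @param d_ff Feed-forward hidden width (default `2 * d`).
#' @param d_cov Covariate embedding width.
#' @param d_r Tissue embedding width.
#' @param n_covariates Covariate vector length K (age_z, sex by default).
#' @param dropout Dropout rate after attention and feed-forward sublayers.
#' @param full_attention_last_block Kept for config compatibility; the final
#'   block always computes and stores full attention.
#' @return An object of class `methformer_spec`.
#' @export
model_spec <- function(P, n_tissues, n_classes = 2L,
                       conv_channels = c(8L, 16L), conv_kernel = 9L,
                       pools = c(4L, 4L), n_layers = 2L, n_heads = 4L,
                       d_ff = NULL, d_cov = 8L, d_r = 8L, n_covariates = 2L,
                       dropout = 0.1, full_attention_last_block = TRUE) {
  check_scalar(P, "P", "integer", lower = 1)
  check_scalar(n_tissues, "n_tissues", "integer", lower = 1)
  check_scalar(n_classes, "n_classes", "integer", lower = 2)
  check_scalar(conv_kernel, "conv_kernel", "integer", lower = 1)
  if (conv_kernel %% 2 == 0) stop_field("conv_kernel", "must be odd")
  if (length(conv_channels) != length(pools)) {
    stop_field("pools", "must have one pooling width per convolution stage")
  }
  check_scalar(n_layers, "n_layers", "integer", lower = 1)
  check_scalar(n_heads, "n_heads", "integer", lower = 1)
  check_scalar(dropout, "dropout", "numeric", lower = 0, upper = 1, upper_open = TRUE)
  if (P < conv_kernel) stop_field("P", "must be at least conv_kernel")
  d <- as.integer(conv_channels[length(conv_channels)])
  if (d %% n_heads != 0) stop_field("n_heads", "must divide the token width d")
  L <- P
  for (p in pools) L <- ceiling(L / p)
  if (L > P / 4) {
    stop_field("pools", sprintf("token count L=%d exceeds P/4=%g; increase pooling", L, P / 4))
  }
  if (is.null(d_ff)) d_ff <- 2L * d
  structure(list(
    P = as.integer(P), n_tissues = as.integer(n_tissues),
    n_classes = as.integer(n_classes),
    conv_channels = as.integer(conv_channels), conv_kernel = as.integer(conv_kernel),
    pools = as.integer(pools), L = as.integer(L), d = d,
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    d_ff = as.integer(d_ff), d_cov = as.integer(d_cov), d_r = as.integer(d_r),
    n_covariates = as.integer(n_covariates), dropout = dropout,
    full_attention_last_block = TRUE
  ), class = "methformer_spec")
}

#' @export
print.methformer_spec <- function(x, ...) {
  cat(sprintf(
    "methformer spec: P=%d -> L=%d tokens (d=%d), conv %s (kernel %d, pools %s), %d transformer layer(s) x %d heads, d_cov=%d, d_r=%d, %d tissues, %d classes\n",
    x$P, x$L, x$d, paste(x$conv_channels, collapse = "-"), x$conv_kernel,
    paste(x$pools, collapse = "-"), x$n_layers, x$n_heads, x$d_cov, x$d_r,
    x$n_tissues, x$n_classes
  ))
  invisible(x)
}

#' Initialize model parameters
#'
#' Projection weights start near identity (w ~ N(1, 0.05), b = 0) so the
#' margin map begins as a lightly perturbed copy of the beta profile; all
#' dense weights use scaled Gaussian initialization.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialization stream.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(spec, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    p <- list()
    p$proj_w <- stats::rnorm(spec$P, mean = 1, sd = 0.05)
    p$proj_b <- rep(0, spec$P)
    Cin <- 1L
    for (s in seq_along(spec$conv_channels)) {
      Cout <- spec$conv_channels[s]
      fan_in <- spec$conv_kernel * Cin
      p[[paste0("conv", s, "_W")]] <-
        matrix(stats::rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)), fan_in, Cout)
      p[[paste0("conv", s, "_b")]] <- rep(0, Cout)
      Cin <- Cout
    }
    d <- spec$d
    for (l in seq_len(spec$n_layers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(pre, nm)]] <- matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
      }
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- matrix(stats::rnorm(d * spec$d_ff, sd = sqrt(2 / d)), d, spec$d_ff)
      p[[paste0(pre, "b1")]] <- rep(0, spec$d_ff)
      p[[paste0(pre, "W2")]] <- matrix(stats::rnorm(spec$d_ff * d, sd = sqrt(2 / spec$d_ff)),
                                       spec$d_ff, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$lnf_g <- rep(1, d); p$lnf_b <- rep(0, d)
    p$cov_W <- matrix(stats::rnorm(spec$n_covariates * spec$d_cov, sd = 0.1),
                      spec$n_covariates, spec$d_cov)
    p$cov_b <- rep(0, spec$d_cov)
    p$tissue_E <- matrix(stats::rnorm(spec$n_tissues * spec$d_r, sd = 0.1),
                         spec$n_tissues, spec$d_r)
    d_u <- d + spec$d_cov + spec$d_r
    p$head_W <- matrix(stats::rnorm(d_u * spec$n_classes, sd = sqrt(1 / d_u)),
                       d_u, spec$n_classes)
    p$head_b <- rep(0, spec$n_classes)
    p
  })
}

#' Closed-form parameter count
#'
#' The projection contributes `2P` parameters, so the total scales linearly in
#' the number of CpG sites.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  d <- spec$d
  n <- 2 * spec$P
  Cin <- 1L
  for (Cout in spec$conv_channels) {
    n <- n + spec$conv_kernel * Cin * Cout + Cout
    Cin <- Cout
  }
  per_layer <- 4 * d +                    # two layernorms
    4 * (d * d + d) +                     # q, k, v, o projections
    d * spec$d_ff + spec$d_ff + spec$d_ff * d + d
  n <- n + spec$n_layers * per_layer + 2 * d
  n <- n + spec$n_covariates * spec$d_cov + spec$d_cov
  n <- n + spec$n_tissues * spec$d_r
  d_u <- d + spec$d_cov + spec$d_r
  as.integer(n + d_u * spec$n_classes + spec$n_classes)
}

# --- receptive-field geometry --------------------------------------------------

# CpG-index centers of the positions of the post-GELU feature map at `stage`
# (before that stage's pooling).
stage_centers <- function(spec, stage) {
  q <- if (stage > 1) prod(spec$pools[seq_len(stage - 1)]) else 1L
  len <- spec$P
  if (stage > 1) for (s in seq_len(stage - 1)) len <- ceiling(len / spec$pools[s])
  (seq_len(len) - 0.5) * q + 0.5
}

#' Receptive-field bounds of each token on the CpG axis
#'
#' Token `t` aggregates a contiguous CpG window: the pooled footprint
#' `(t-1)*q + 1 .. t*q` (q = product of pooling widths) widened by the
#' cumulative convolution half-widths, clipped to `[1, P]`.
#'
#' @param spec A [model_spec()].
#' @return Data frame with columns token, start, end, center.
#' @export
token_receptive_fields <- function(spec) {
  q <- prod(spec$pools)
  half <- (spec$conv_kernel - 1L) %/% 2L
  widen <- 0
  scale <- 1
  for (s in seq_along(spec$pools)) {
    widen <- widen + half * scale
    scale <- scale * spec$pools[s]
  }
  t <- seq_len(spec$L)
  data.frame(
    token = t,
    start = pmax(1, (t - 1) * q + 1 - widen),
    end = pmin(spec$P, t * q + widen),
    center = pmin(spec$P, (t - 0.5) * q + 0.5)
  )
}

# --- forward pass ---------------------------------------------------------------

#' CpG-wise linear projection (margin map)
#'
#' `h[p] = w[p] * x[p] + b[p]`: strictly elementwise, no cross-site mixing.
#'
#' @param x Length-P beta vector or B x P matrix.
#' @param w,b Length-P weight and bias vectors.
#' @return Margin map with the shape of `x`.
#' @export
cpg_project <- function(x, w, b) {
  if (is.matrix(x)) {
    if (ncol(x) != length(w)) stop("length mismatch: x has ", ncol(x),
                                   " sites, projection has ", length(w), call. = FALSE)
    return(sweep(sweep(x, 2, w, "*"), 2, b, "+"))
  }
  if (length(x) != length(w)) stop("length mismatch: x has ", length(x),
                                   " sites, projection has ", length(w), call. = FALSE)
  w * x + b
}

conv_stack_forward <- function(params, spec, H, keep = FALSE) {
  B <- nrow(H)
  A <- array(H, c(B, ncol(H), 1L))
  stages <- vector("list", length(spec$conv_channels))
  Cin <- 1L
  for (s in seq_along(spec$conv_channels)) {
    cf <- conv1d_forward(A, params[[paste0("conv", s, "_W")]],
                         params[[paste0("conv", s, "_b")]], spec$conv_kernel)
    gf <- gelu_forward(cf$out)
    pf <- maxpool_forward(gf$out, spec$pools[s])
    stages[[s]] <- list(
      pre = if (keep) cf$out else NULL,
      gate = if (keep) gf$s else NULL,
      inp = if (keep) A else NULL,
      act = gf$out,        # post-GELU, pre-pool map (Grad-CAM++ target)
      pool = if (keep) pf[c("arg", "P", "pool")] else NULL,
      Cin = Cin
    )
    A <- pf$out
    Cin <- spec$conv_channels[s]
  }
  # add sinusoidal positional encodings on the token index
  L <- dim(A)[2]
  pe <- positional_encoding(L, spec$d)
  Tm <- as_mat(A) + pe[rep(seq_len(L), each = B), , drop = FALSE]
  list(tokens = as_arr(Tm, B, L), stages = stages, pe = pe)
}

#' Convolutional tokenizer
#'
#' Encodes a margin map into a token sequence of shape `L x d` (GELU
#' convolution stages with max pooling) and adds index-based sinusoidal
#' positional encodings.
#'
#' @param h Length-P margin map or B x P matrix.
#' @param params,spec Model parameters and [model_spec()].
#' @return `L x d` matrix for a vector input, `B x L x d` array otherwise.
#' @export
conv_encode <- function(h, params, spec) {
  single <- !is.matrix(h)
  H <- if (single) matrix(h, 1) else h
  if (ncol(H) < spec$conv_kernel) {
    stop("input length ", ncol(H), " is smaller than the convolution kernel", call. = FALSE)
  }
  tok <- conv_stack_forward(params, spec, H)$tokens
  if (single) matrix(tok[1, , ], dim(tok)[2], dim(tok)[3]) else tok
}

transformer_stack_forward <- function(params, spec, Tarr, training = FALSE, keep = FALSE) {
  B <- dim(Tarr)[1]; L <- dim(Tarr)[2]; d <- dim(Tarr)[3]
  X <- Tarr
  layers <- vector("list", spec$n_layers)
  attn_final <- NULL
  for (l in seq_len(spec$n_layers)) {
    pre <- paste0("l", l, "_")
    Xm <- as_mat(X)
    ln1 <- layernorm_forward(Xm, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    mp <- list(Wq = params[[paste0(pre, "Wq")]], bq = params[[paste0(pre, "bq")]],
               Wk = params[[paste0(pre, "Wk")]], bk = params[[paste0(pre, "bk")]],
               Wv = params[[paste0(pre, "Wv")]], bv = params[[paste0(pre, "bv")]],
               Wo = params[[paste0(pre, "Wo")]], bo = params[[paste0(pre, "bo")]])
    mh <- mha_forward(as_arr(ln1$out, B, L), mp, spec$n_heads)
    dr1 <- dropout_forward(as_mat(mh$out), spec$dropout, training)
    X1m <- Xm + dr1$out
    ln2 <- layernorm_forward(X1m, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    ff_pre <- sweep(ln2$out %*% params[[paste0(pre, "W1")]], 2, params[[paste0(pre, "b1")]], "+")
    fg <- gelu_forward(ff_pre)
    ff_out <- sweep(fg$out %*% params[[paste0(pre, "W2")]], 2, params[[paste0(pre, "b2")]], "+")
    dr2 <- dropout_forward(ff_out, spec$dropout, training)
    X2m <- X1m + dr2$out
    if (any(!is.finite(X2m))) {
      stop(sprintf("non-finite activations in transformer layer %d", l), call. = FALSE)
    }
    if (l == spec$n_layers) attn_final <- mh$cache$attn
    layers[[l]] <- if (keep) list(ln1 = ln1, mha = mh$cache, dr1 = dr1, X1m = X1m,
                                  ln2 = ln2, ff_pre = ff_pre, ff_gate = fg$s,
                                  ff_act = fg$out, dr2 = dr2, Xin = Xm) else NULL
    X <- as_arr(X2m, B, L)
  }
  Xm <- as_mat(X)
  lnf <- layernorm_forward(Xm, params$lnf_g, params$lnf_b)
  list(H_final = as_arr(lnf$out, B, L), attention = attn_final,
       layers = layers, lnf = if (keep) lnf else NULL, pre_lnf = if (keep) Xm else NULL)
}

#' Transformer backbone forward pass
#'
#' Pre-norm residual blocks (self-attention + feed-forward). The final block's
#' per-head attention matrices are returned; every attention row sums to 1.
#'
#' @param T Token matrix `L x d` (single sample) or `B x L x d` array.
#' @param params,spec Model parameters and [model_spec()].
#' @return List with `H_final` (same shape as input) and `attention` (for a
#'   single sample, a list of H `L x L` matrices; batched, a list per sample).
#' @export
transformer_forward <- function(T, params, spec) {
  single <- is.matrix(T)
  Tarr <- if (single) array(T, c(1L, nrow(T), ncol(T))) else T
  if (any(!is.finite(Tarr))) stop("non-finite token inputs", call. = FALSE)
  res <- transformer_stack_forward(params, spec, Tarr, training = FALSE)
  if (single) {
    list(H_final = matrix(res$H_final[1, , ], dim(Tarr)[2], dim(Tarr)[3]),
         attention = res$attention[[1]])
  } else {
    list(H_final = res$H_final, attention = res$attention)
  }
}

mean_pool_tokens <- function(Harr) {
  # (B, L, d) -> (B, d) column-wise mean over the token axis
  colSums(aperm(Harr, c(2, 1, 3)), dims = 1) / dim(Harr)[2]
}

#' Fuse pooled tokens with covariate and tissue embeddings
#'
#' Concatenation order: mean-pooled tokens (D), covariate embedding (d_cov),
#' tissue embedding row (d_r). Tissue information enters the model only here.
#'
#' @param H_final `L x d` token matrix (or `B x L x d` array).
#' @param z Covariate vector (or B x K matrix).
#' @param r Tissue code(s), 0-based.
#' @param params,spec Model parameters and [model_spec()].
#' @return Length `D + d_cov + d_r` vector (or B-row matrix).
#' @export
fuse <- function(H_final, z, r, params, spec) {
  single <- is.matrix(H_final)
  Harr <- if (single) array(H_final, c(1L, nrow(H_final), ncol(H_final))) else H_final
  Z <- if (is.matrix(z)) z else matrix(z, nrow = dim(Harr)[1], byrow = TRUE)
  r <- as.integer(r)
  if (any(r < 0 | r >= spec$n_tissues)) {
    stop("unseen tissue code: ", paste(unique(r[r < 0 | r >= spec$n_tissues]), collapse = ", "),
         call. = FALSE)
  }
  pooled <- mean_pool_tokens(Harr)
  cov_e <- sweep(Z %*% params$cov_W, 2, params$cov_b, "+")
  tis_e <- params$tissue_E[r + 1L, , drop = FALSE]
  u <- cbind(pooled, cov_e, tis_e)
  if (single) drop(u) else u
}

#' Softmax classifier head
#'
#' @param u Fused representation vector (or B-row matrix).
#' @param params Model parameters.
#' @return Probability vector (or matrix); entries positive, rows sum to 1.
#' @export
classify <- function(u, params) {
  U <- if (is.matrix(u)) u else matrix(u, 1)
  if (any(!is.finite(U))) stop("non-finite fused representation", call. = FALSE)
  logits <- sweep(U %*% params$head_W, 2, params$head_b, "+")
  pr <- softmax_rows(logits)
  if (is.matrix(u)) pr else drop(pr)
}

#' Full forward pass
#'
#' @param params Parameter list from [init_params()] or a fitted model.
#' @param spec A [model_spec()].
#' @param X B x P beta matrix.
#' @param Z B x K covariate matrix.
#' @param tissue Integer tissue codes (0-based), length B.
#' @param training Logical; enables dropout (stochastic). Evaluation mode is
#'   deterministic.
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return List with `probs` (B x C), `logits`, `margins` (B x P margin map),
#'   `attention` (final-block per-sample, per-head L x L matrices), and
#'   `cache` when requested.
#' @export
model_forward <- function(params, spec, X, Z, tissue, training = FALSE,
                          keep_cache = FALSE) {
  if (ncol(X) != spec$P) stop("X has ", ncol(X), " sites; spec expects ", spec$P, call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite beta inputs", call. = FALSE)
  B <- nrow(X)
  tissue <- as.integer(tissue)
  if (any(tissue < 0 | tissue >= spec$n_tissues)) {
    stop("unseen tissue code", call. = FALSE)
  }
  H <- cpg_project(X, params$proj_w, params$proj_b)
  conv <- conv_stack_forward(params, spec, H, keep = keep_cache)
  trans <- transformer_stack_forward(params, spec, conv$tokens,
                                     training = training, keep = keep_cache)
  pooled <- mean_pool_tokens(trans$H_final)
  cov_e <- sweep(Z %*% params$cov_W, 2, params$cov_b, "+")
  tis_e <- params$tissue_E[tissue + 1L, , drop = FALSE]
  u <- cbind(pooled, cov_e, tis_e)
  logits <- sweep(u %*% params$head_W, 2, params$head_b, "+")
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, margins = H, attention = trans$attention)
  if (keep_cache) {
    out$cache <- list(X = X, Z = Z, tissue = tissue, H = H, conv = conv,
                      trans = trans, u = u, B = B)
  }
  out
}

# Backward pass. `dlogits` is the gradient at the logits; `dmargins` is an
# optional gradient applied directly to the margin map (the hinge margin
# regularizer enters here). Returns parameter gradients and, when
# `conv_grads = TRUE`, the gradient of the objective with respect to each
# post-GELU convolution feature map (used by Grad-CAM++).
model_backward <- function(params, spec, cache, dlogits, dmargins = NULL,
                           conv_grads = FALSE) {
  B <- cache$B
  g <- list()
  g$head_W <- crossprod(cache$u, dlogits)
  g$head_b <- colSums(dlogits)
  du <- dlogits %*% t(params$head_W)
  d <- spec$d
  dpooled <- du[, seq_len(d), drop = FALSE]
  dcov_e <- du[, d + seq_len(spec$d_cov), drop = FALSE]
  dtis_e <- du[, d + spec$d_cov + seq_len(spec$d_r), drop = FALSE]
  g$cov_W <- crossprod(cache$Z, dcov_e)
  g$cov_b <- colSums(dcov_e)
  g$tissue_E <- matrix(0, spec$n_tissues, spec$d_r)
  agg <- rowsum(dtis_e, group = cache$tissue)
  g$tissue_E[as.integer(rownames(agg)) + 1L, ] <- agg
  L <- spec$L
  # mean pooling: every token row receives dpooled / L
  dHf <- dpooled[rep(seq_len(B), times = L), , drop = FALSE] / L
  lb <- layernorm_backward(dHf, cache$trans$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(spec$n_layers))) {
    pre <- paste0("l", l, "_")
    lc <- cache$trans$layers[[l]]
    # residual 2: X2 = X1 + dropout(ffn(ln2(X1)))
    dff_out <- dropout_backward(dX, lc$dr2)
    g[[paste0(pre, "W2")]] <- crossprod(lc$ff_act, dff_out)
    g[[paste0(pre, "b2")]] <- colSums(dff_out)
    dff_act <- dff_out %*% t(params[[paste0(pre, "W2")]])
    dff_pre <- dff_act * gelu_grad_cached(lc$ff_pre, lc$ff_gate)
    g[[paste0(pre, "W1")]] <- crossprod(lc$ln2$out, dff_pre)
    g[[paste0(pre, "b1")]] <- colSums(dff_pre)
    dln2_out <- dff_pre %*% t(params[[paste0(pre, "W1")]])
    lb2 <- layernorm_backward(dln2_out, lc$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX1 <- dX + lb2$dX
    # residual 1: X1 = Xin + dropout(mha(ln1(Xin)))
    dmha_out <- dropout_backward(dX1, lc$dr1)
    mp <- list(Wq = params[[paste0(pre, "Wq")]], Wk = params[[paste0(pre, "Wk")]],
               Wv = params[[paste0(pre, "Wv")]], Wo = params[[paste0(pre, "Wo")]])
    mb <- mha_backward(as_arr(dmha_out, B, L), mp, lc$mha, spec$n_heads)
    for (nm in names(mb$grads)) g[[paste0(pre, nm)]] <- mb$grads[[nm]]
    lb1 <- layernorm_backward(mb$dX, lc$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX1 + lb1$dX
  }
  # positional encodings are fixed; gradient passes through unchanged
  dA <- as_arr(dX, B, L)
  dconv_act <- if (conv_grads) vector("list", length(spec$conv_channels)) else NULL
  for (s in rev(seq_along(spec$conv_channels))) {
    sc <- cache$conv$stages[[s]]
    dact <- maxpool_backward(dA, sc$pool)
    if (conv_grads) dconv_act[[s]] <- dact
    dpre <- dact * gelu_grad_cached(sc$pre, sc$gate)
    cb <- conv1d_backward(dpre, sc$inp, params[[paste0("conv", s, "_W")]],
                          spec$conv_kernel, sc$Cin)
    g[[paste0("conv", s, "_W")]] <- cb$dW
    g[[paste0("conv", s, "_b")]] <- cb$db
    dA <- cb$dA
  }
  dH <- matrix(dA, B, spec$P)
  if (!is.null(dmargins)) dH <- dH + dmargins
  g$proj_w <- colSums(dH * cache$X)
  g$proj_b <- colSums(dH)
  out <- list(grads = g)
  if (conv_grads) out$dconv_act <- dconv_act
  out
}
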