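test_that("model_spec validates its geometry", {
  expect_error(model_spec(P = 32L, n_tissues = 2L, conv_kernel = 4L), "odd")
  expect_error(model_spec(P = 32L, n_tissues = 2L, conv_channels = c(4L, 6L),
                          pools = c(2L, 2L), n_heads = 4L), "n_heads")
  expect_error(model_spec(P = 32L, n_tissues = 2L, conv_channels = c(4L, 4L),
                          pools = c(1L, 1L), n_heads = 2L), "pools")
  expect_error(model_spec(P = 32L, n_tissues = 2L, conv_channels = 8L,
                          pools = c(2L, 2L)), "pools")
  spec <- tiny_spec()
  expect_equal(spec$L, ceiling(32 / 4))
  expect_equal(spec$d, 4L)
})

test_that("count_params equals the length of the initialized parameter vector", {
  for (s in list(tiny_spec(),
                 model_spec(P = 100L, n_tissues = 3L, n_classes = 4L,
                            conv_channels = c(5L, 6L), conv_kernel = 5L,
                            pools = c(5L, 5L), n_layers = 3L, n_heads = 3L,
                            d_cov = 4L, d_r = 5L))) {
    p <- init_params(s, seed = 1L)
    expect_identical(count_params(s), length(unlist(p)))
  }
})

test_that("initialization is seed-deterministic and leaves the caller RNG alone", {
  spec <- tiny_spec()
  set.seed(123); before <- runif(1)
  set.seed(123)
  p1 <- init_params(spec, seed = 5L)
  after <- runif(1)
  expect_identical(before, after)  # with_seed restored the RNG state
  p2 <- init_params(spec, seed = 5L)
  expect_identical(p1, p2)
  p3 <- init_params(spec, seed = 6L)
  expect_false(identical(p1$proj_w, p3$proj_w))
})

test_that("the CpG projection is strictly local (depthwise)", {
  set.seed(2)
  P <- 50L
  w <- rnorm(P); b <- rnorm(P); x <- runif(P)
  h <- cpg_project(x, w, b)
  expect_equal(h, w * x + b)
  for (p in sample.int(P, 10)) {
    x2 <- x; x2[p] <- x2[p] + 0.37
    h2 <- cpg_project(x2, w, b)
    expect_identical(which(h2 != h), p)
  }
  # matrix input, and length checking
  X <- matrix(runif(3 * P), 3)
  expect_equal(cpg_project(X, w, b)[2, ], w * X[2, ] + b)
  expect_error(cpg_project(runif(P + 1), w, b), "length mismatch")
})

test_that("conv1d matches a brute-force same-padding convolution", {
  conv_oracle <- function(A, W, b, kernel) {
    d <- dim(A); B <- d[1]; P <- d[2]; Cin <- d[3]; Cout <- ncol(W)
    half <- (kernel - 1) / 2
    out <- array(0, c(B, P, Cout))
    for (bb in 1:B) for (p in 1:P) for (co in 1:Cout) {
      acc <- b[co]
      for (o in 1:kernel) for (ci in 1:Cin) {
        q <- p + o - half - 1
        if (q >= 1 && q <= P) acc <- acc + A[bb, q, ci] * W[(o - 1) * Cin + ci, co]
      }
      out[bb, p, co] <- acc
    }
    out
  }
  set.seed(4)
  for (i in 1:5) {
    B <- sample(1:3, 1); P <- sample(7:15, 1); Cin <- sample(1:3, 1)
    Cout <- sample(1:4, 1); kernel <- sample(c(3L, 5L), 1)
    A <- array(rnorm(B * P * Cin), c(B, P, Cin))
    W <- matrix(rnorm(kernel * Cin * Cout), kernel * Cin, Cout)
    b <- rnorm(Cout)
    got <- methformer:::conv1d_forward(A, W, b, kernel)$out
    expect_equal(got, conv_oracle(A, W, b, kernel), tolerance = 1e-12)
  }
})

test_that("max pooling matches an apply() oracle and handles ragged tails", {
  set.seed(5)
  A <- array(rnorm(2 * 11 * 3), c(2, 11, 3))
  pf <- methformer:::maxpool_forward(A, 4L)
  expect_equal(dim(pf$out), c(2L, 3L, 3L))
  for (b in 1:2) for (c in 1:3) {
    x <- A[b, , c]
    oracle <- vapply(1:3, function(t) max(x[((t - 1) * 4 + 1):min(11, t * 4)]),
                     numeric(1))
    expect_equal(pf$out[b, , c], oracle)
  }
})

test_that("conv_encode yields L x d tokens and rejects short inputs", {
  spec <- tiny_spec()
  params <- init_params(spec, 1L)
  tok <- conv_encode(runif(spec$P), params, spec)
  expect_equal(dim(tok), c(spec$L, spec$d))
  expect_error(conv_encode(runif(2), params, spec), "smaller than the convolution kernel")
})

test_that("positional encodings follow the sinusoidal formula", {
  pe <- methformer:::positional_encoding(6L, 4L)
  for (pos in 0:5) for (j in 1:2) {
    freq <- 1 / 10000^((2 * (j - 1)) / 4)
    expect_equal(pe[pos + 1, 2 * j - 1], sin(pos * freq))
    expect_equal(pe[pos + 1, 2 * j], cos(pos * freq))
  }
})

test_that("transformer attention rows are stochastic and shapes are preserved", {
  spec <- tiny_spec()
  params <- init_params(spec, 2L)
  T1 <- matrix(rnorm(spec$L * spec$d), spec$L, spec$d)
  res <- transformer_forward(T1, params, spec)
  expect_equal(dim(res$H_final), dim(T1))
  expect_length(res$attention, spec$n_heads)
  for (A in res$attention) {
    expect_equal(dim(A), c(spec$L, spec$L))
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, spec$L), tolerance = 1e-12)
  }
  expect_error(transformer_forward(T1 * NA, params, spec), "non-finite")
})

test_that("forward pass returns valid probabilities, batches consistently, and is deterministic in eval mode", {
  spec <- tiny_spec()
  params <- init_params(spec, 3L)
  inp <- tiny_inputs(spec, B = 5L)
  fw <- model_forward(params, spec, inp$X, inp$Z, inp$tissue)
  expect_equal(dim(fw$probs), c(5L, 2L))
  expect_true(all(fw$probs > 0))
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-12)
  expect_equal(fw$margins, cpg_project(inp$X, params$proj_w, params$proj_b))
  # batching equivalence
  single <- t(vapply(1:5, function(i) {
    model_forward(params, spec, inp$X[i, , drop = FALSE],
                  inp$Z[i, , drop = FALSE], inp$tissue[i])$probs[1, ]
  }, numeric(2)))
  expect_equal(fw$probs, single, tolerance = 1e-12)
  # eval-mode determinism (bitwise)
  fw2 <- model_forward(params, spec, inp$X, inp$Z, inp$tissue)
  expect_identical(fw$probs, fw2$probs)
  expect_error(model_forward(params, spec, inp$X, inp$Z, rep(9L, 5)),
               "unseen tissue")
})

test_that("analytic gradients agree with finite differences", {
  spec <- tiny_spec()
  params <- init_params(spec, 2L)
  inp <- tiny_inputs(spec, B = 4L, seed = 3L)
  lcfg <- loss_config(epsilon = 0.1, alpha = 0.3, top_k = 5L)
  loss_at <- function(p) {
    fw <- model_forward(p, spec, inp$X, inp$Z, inp$tissue)
    total_loss(inp$y, fw$probs, fw$margins, lcfg)
  }
  fw <- model_forward(params, spec, inp$X, inp$Z, inp$tissue, keep_cache = TRUE)
  lg <- methformer:::total_loss_grads(inp$y, fw$probs, fw$margins, lcfg)
  bk <- methformer:::model_backward(params, spec, fw$cache, lg$dlogits, lg$dmargins)
  expect_setequal(names(bk$grads), names(params))
  eps <- 1e-5
  set.seed(9)
  for (nm in names(bk$grads)) {
    g <- bk$grads[[nm]]
    for (i in sample(length(g), min(3, length(g)))) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      fd <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-4, abs(fd) + abs(g[i])), 1e-4)
    }
  }
})

test_that("token receptive fields tile the CpG axis in order", {
  spec <- tiny_spec(P = 64L)
  rf <- token_receptive_fields(spec)
  expect_equal(nrow(rf), spec$L)
  expect_true(all(rf$start >= 1 & rf$end <= spec$P))
  expect_true(all(rf$start <= rf$center & rf$center <= rf$end + 0.5))
  expect_true(all(diff(rf$center) > 0))
  # every CpG is covered by at least one token
  covered <- rep(FALSE, spec$P)
  for (t in seq_len(nrow(rf))) covered[rf$start[t]:rf$end[t]] <- TRUE
  expect_true(all(covered))
})

test_that("fuse concatenates pooled tokens, covariate embedding, tissue row", {
  spec <- tiny_spec()
  params <- init_params(spec, 4L)
  H <- matrix(rnorm(spec$L * spec$d), spec$L, spec$d)
  z <- rnorm(spec$n_covariates)
  u <- fuse(H, z, 1L, params, spec)
  expect_length(u, spec$d + spec$d_cov + spec$d_r)
  expect_equal(u[1:spec$d], colMeans(H))
  expect_equal(u[(spec$d + 1):(spec$d + spec$d_cov)],
               as.numeric(z %*% params$cov_W + params$cov_b))
  expect_equal(u[(spec$d + spec$d_cov + 1):length(u)], params$tissue_E[2, ])
  expect_error(fuse(H, z, 5L, params, spec), "unseen tissue")
  pr <- classify(u, params)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})
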