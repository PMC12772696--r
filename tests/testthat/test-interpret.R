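# A fast fitted model shared across interpretability tests.
fit_for_interpret <- local({
  fit <- NULL
  cohort <- NULL
  function() {
    if (is.null(fit)) {
      cohort <<- tiny_cohort(seed = 31L, n = 20L, P = 48L, n_causal = 6L,
                             effect = 0.4)
      fit <<- methformer(cohort$beta, cohort$samples,
                         spec_args = tiny_spec_args(),
                         train = fast_train(), seed = 4L)
    }
    list(fit = fit, cohort = cohort)
  }
})

test_that("linear importance exposes signed weights and their magnitudes", {
  env <- fit_for_interpret()
  li <- linear_importance(env$fit)
  expect_identical(names(li$signed), env$fit$cpg_ids)
  expect_equal(unname(li$magnitudes$values), abs(unname(li$signed)))
  expect_identical(unname(li$signed), unname(coef(env$fit)))
})

test_that("rank enrichment p-values separate planted from random site sets", {
  values <- c(rep(5, 10) + runif(10), runif(90))  # sites 1-10 clearly largest
  top <- rank_enrichment_test(values, 1:10, n_perm = 2000L, seed = 1L)
  expect_lt(top$p, 0.01)
  expect_equal(top$statistic, mean(rank(values)[1:10]))
  bottom <- rank_enrichment_test(values, 91:100, n_perm = 2000L, seed = 1L)
  expect_gt(bottom$p, 0.5)
  # determinism
  expect_identical(top$p, rank_enrichment_test(values, 1:10, 2000L, 1L)$p)
})

test_that("Grad-CAM++ maps are non-negative, P-long, and stage-validated", {
  env <- fit_for_interpret()
  fit <- env$fit
  x <- env$cohort$beta[1, fit$cpg_ids]
  nd <- methformer:::prepare_newdata(fit, env$cohort$beta, env$cohort$samples)
  sal <- gradcam_pp(fit, x, nd$Z[1, ], nd$tissue[1], class_index = 1L)
  expect_s3_class(sal, "methformer_saliency")
  expect_length(sal$values, fit$spec$P)
  expect_identical(names(sal$values), fit$cpg_ids)
  expect_true(all(sal$values >= 0))
  # fine-grained stage also works
  sal1 <- gradcam_pp(fit, x, nd$Z[1, ], nd$tissue[1], layer_choice = 1L)
  expect_true(all(sal1$values >= 0))
  expect_error(gradcam_pp(fit, x, nd$Z[1, ], nd$tissue[1], layer_choice = 9L),
               "unknown convolution stage")
  expect_error(gradcam_pp(fit, x, nd$Z[1, ], nd$tissue[1], class_index = 5L),
               "class_index")
})

test_that("tissue-wise Grad-CAM++ profiles average tissues, not samples", {
  env <- fit_for_interpret()
  prof <- gradcam_tissue_profile(env$fit, env$cohort$beta, env$cohort$samples)
  expect_equal(nrow(prof$per_tissue), 2L)
  expect_equal(unname(prof$overall), unname(colMeans(prof$per_tissue)))
  expect_equal(unname(prof$n_per_tissue), as.integer(table(env$cohort$samples$tissue)))
  # sample-weighted averaging is available and differs in general
  prof2 <- gradcam_tissue_profile(env$fit, env$cohort$beta, env$cohort$samples,
                                  average = "samples")
  w <- prof$n_per_tissue / sum(prof$n_per_tissue)
  expect_equal(unname(prof2$overall),
               unname(w[1] * prof$per_tissue[1, ] + w[2] * prof$per_tissue[2, ]),
               tolerance = 1e-10)
})

test_that("exact Shapley recovers the coefficients of a linear game", {
  set.seed(6)
  P <- 10L
  cf <- rnorm(P)
  f <- function(X) as.numeric(X %*% cf)
  x <- runif(P); bg <- runif(P)
  sh <- shapley_exact(f, x, bg, features = 1:P)
  expect_equal(sh$phi, cf * (x - bg), tolerance = 1e-10)
  expect_equal(sum(sh$phi), f(matrix(x, 1)) - f(matrix(bg, 1)), tolerance = 1e-10)
  expect_error(shapley_exact(f, runif(20), runif(20), 1:15), "14 features")
})

test_that("grouped features attribute whole windows", {
  f <- function(X) X[, 1] * X[, 2] + X[, 3]
  x <- c(1, 1, 1, 5); bg <- c(0, 0, 0, 5)
  sh <- shapley_exact(f, x, bg, features = list(1:2, 3L))
  expect_length(sh$phi, 2L)
  expect_equal(sum(sh$phi), f(matrix(x, 1)) - f(matrix(bg, 1)))
  expect_equal(sh$phi, c(1, 1))  # the interaction sits fully in window 1
  # coordinates outside every group keep the explained sample's value
  got <- methformer:::substitute_features(x, bg, list(1:2), integer(0))
  expect_equal(got, c(0, 0, 1, 5))
})

test_that("sampled Shapley converges to exact with a valid standard error", {
  set.seed(7)
  P <- 6L
  f <- function(X) sin(X[, 1]) + X[, 2] * X[, 3] + 0.5 * X[, 4]^2 - X[, 5] * X[, 6]
  x <- runif(P); bg <- runif(P)
  ex <- shapley_exact(f, x, bg, 1:P)
  sm <- shapley_sampled(f, x, bg, 1:P, n_permutations = 4000L, seed = 2L)
  expect_length(sm$se, P)
  expect_true(all(is.finite(sm$se)))
  expect_true(all(abs(sm$phi - ex$phi) <= 4 * pmax(sm$se, 1e-8)))
  # the permutation estimator preserves efficiency exactly per permutation
  expect_equal(sum(sm$phi), f(matrix(x, 1)) - f(matrix(bg, 1)), tolerance = 1e-10)
  # deterministic per seed
  sm2 <- shapley_sampled(f, x, bg, 1:P, n_permutations = 50L, seed = 9L)
  sm3 <- shapley_sampled(f, x, bg, 1:P, n_permutations = 50L, seed = 9L)
  expect_identical(sm2$phi, sm3$phi)
})

test_that("background policies pick controls as documented", {
  env <- fit_for_interpret()
  beta <- env$cohort$beta; samples <- env$cohort$samples
  controls <- samples$sample_id[samples$diagnosis == 0]
  centroid <- colMeans(beta[controls, ])
  bg_mean <- methformer:::choose_background(beta, samples, "control_mean")
  expect_equal(bg_mean$x, centroid)
  bg_near <- methformer:::choose_background(beta, samples, "nearest_control")
  expect_true(bg_near$id %in% controls)
  d2 <- rowSums(sweep(beta[controls, ], 2, centroid)^2)
  expect_identical(bg_near$id, controls[which.min(d2)])
  sid <- samples$sample_id[3]
  expect_identical(methformer:::choose_background(beta, samples, sid)$id, sid)
  expect_error(methformer:::choose_background(beta, samples, "bogus"),
               "unknown background policy")
})

test_that("cohort SHAP profiles spread window attributions over CpGs", {
  env <- fit_for_interpret()
  sub <- env$cohort$samples[c(1:3, 21:23), ]
  prof <- shap_cohort_profile(env$fit, env$cohort$beta, sub,
                              window_size = 12L, n_permutations = 8L, seed = 1L)
  P <- env$fit$spec$P
  expect_length(prof$mean_phi, P)
  expect_equal(dim(prof$per_sample), c(6L, ceiling(P / 12)))
  # spreading preserves the total attribution
  expect_equal(sum(prof$mean_phi), sum(colMeans(prof$per_sample)), tolerance = 1e-10)
  expect_true(prof$background_id %in% env$cohort$samples$sample_id)
})

test_that("attention analysis returns stochastic maps with bounded entropy", {
  env <- fit_for_interpret()
  fit <- env$fit
  nd <- methformer:::prepare_newdata(fit, env$cohort$beta, env$cohort$samples)
  att <- attention_analysis(fit, nd$X[2, ], nd$Z[2, ], nd$tissue[2])
  L <- fit$spec$L
  expect_length(att$per_head, fit$spec$n_heads)
  expect_equal(att$averaged, Reduce(`+`, att$per_head) / length(att$per_head))
  expect_equal(rowSums(att$averaged), rep(1, L), tolerance = 1e-12)
  expect_true(all(att$row_entropies >= 0 & att$row_entropies <= log(L) + 1e-12))
  expect_output(print(att), "attention bundle")
})

test_that("attention is independent of the tissue code by construction", {
  env <- fit_for_interpret()
  fit <- env$fit
  nd <- methformer:::prepare_newdata(fit, env$cohort$beta, env$cohort$samples)
  a0 <- attention_analysis(fit, nd$X[1, ], nd$Z[1, ], 0L)
  a1 <- attention_analysis(fit, nd$X[1, ], nd$Z[1, ], 1L)
  expect_identical(a0$per_head, a1$per_head)
  # ... while the predicted probabilities may differ with tissue
  p0 <- model_forward(fit$params, fit$spec, nd$X[1, , drop = FALSE],
                      nd$Z[1, , drop = FALSE], 0L)$probs
  p1 <- model_forward(fit$params, fit$spec, nd$X[1, , drop = FALSE],
                      nd$Z[1, , drop = FALSE], 1L)$probs
  expect_false(identical(p0, p1))
})

test_that("attribution tables export all requested curves", {
  env <- fit_for_interpret()
  path <- tempfile(fileext = ".tsv")
  P <- env$fit$spec$P
  write_attributions(env$fit, path, gradcampp = runif(P), mean_shap = rnorm(P))
  df <- read.delim(path)
  expect_identical(names(df), c("cpg_id", "signed_linear_weight",
                                "abs_linear_weight", "gradcampp", "mean_shap"))
  expect_identical(df$cpg_id, env$fit$cpg_ids)
  expect_equal(df$signed_linear_weight, unname(coef(env$fit)))
})
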