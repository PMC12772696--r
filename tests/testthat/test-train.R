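test_that("weight decay applies to the right parameter groups", {
  cfg <- train_config(weight_decay_projection = 1e-5, weight_decay_rest = 1e-4)
  dr <- methformer:::decay_rate
  expect_equal(dr("proj_w", cfg), 1e-5)
  for (nm in c("l1_Wq", "l2_Wk", "l1_Wv", "l1_Wo", "l1_W1", "l2_W2",
               "conv1_W", "head_W", "cov_W")) {
    expect_equal(dr(nm, cfg), 1e-4)
  }
  for (nm in c("proj_b", "l1_bq", "l1_ln1_g", "l1_ln2_b", "lnf_g",
               "tissue_E", "head_b", "conv1_b", "cov_b")) {
    expect_equal(dr(nm, cfg), 0)
  }
})

test_that("one AdamW step matches the hand-computed update", {
  cfg <- train_config(learning_rate = 0.01, weight_decay_projection = 0.1,
                      weight_decay_rest = 0.2)
  params <- list(proj_w = c(1, 2), l1_Wq = matrix(c(1, -1), 1), proj_b = c(3, 4))
  grads <- list(proj_w = c(0.5, -0.5), l1_Wq = matrix(c(0.1, 0.2), 1),
                proj_b = c(1, 1))
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  upd <- methformer:::adamw_step(params, grads, state, cfg, t = 1L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    m <- (1 - b1) * grads[[nm]] / (1 - b1)
    v <- (1 - b2) * grads[[nm]]^2 / (1 - b2)
    wd <- c(proj_w = 0.1, l1_Wq = 0.2, proj_b = 0)[[nm]]
    want <- params[[nm]] - 0.01 * (m / (sqrt(v) + eps) + wd * params[[nm]])
    expect_equal(unname(as.vector(upd$params[[nm]])), unname(as.vector(want)),
                 tolerance = 1e-12)
  }
})

test_that("train_model improves on separable data and returns the best checkpoint", {
  cohort <- tiny_cohort(seed = 13L, n = 30L, P = 40L, n_causal = 8L, effect = 0.4)
  spec <- model_spec(P = 40L, n_tissues = 2L, conv_channels = c(4L, 8L),
                     conv_kernel = 3L, pools = c(2L, 2L), n_layers = 1L,
                     n_heads = 2L, d_cov = 3L, d_r = 2L, dropout = 0)
  params <- init_params(spec, 1L)
  enc <- encode_covariates(cohort$samples)
  idx_tr <- seq_len(48); idx_va <- 49:60
  data <- list(
    train = list(X = cohort$beta[idx_tr, ], Z = enc$covariates[idx_tr, ],
                 tissue = enc$tissue[idx_tr], y = cohort$samples$diagnosis[idx_tr]),
    val = list(X = cohort$beta[idx_va, ], Z = enc$covariates[idx_va, ],
               tissue = enc$tissue[idx_va], y = cohort$samples$diagnosis[idx_va])
  )
  res <- train_model(params, spec, data,
                     train_config(learning_rate = 3e-3, max_epochs = 8L,
                                  batch_size = 16L, seed = 1L),
                     loss_config())
  expect_true(all(c("epoch", "train_loss", "val_auc") %in% names(res$history)))
  expect_lte(res$best_epoch, nrow(res$history))
  expect_equal(res$best_val_auc, max(res$history$val_auc))
  # the returned parameters reproduce the best recorded validation AUC
  sc <- methformer:::predict_scores(res$params, spec, data$val$X, data$val$Z,
                                    data$val$tissue)
  expect_equal(methformer:::auc_midrank(data$val$y, sc), res$best_val_auc)
  # training reduces the loss relative to the first epoch
  expect_lt(res$history$train_loss[nrow(res$history)], res$history$train_loss[1])
})

test_that("methformer returns a classic modelling object with working methods", {
  cohort <- tiny_cohort(seed = 21L)
  fit <- methformer(cohort$beta, cohort$samples, spec_args = tiny_spec_args(),
                    train = fast_train(), seed = 2L)
  expect_s3_class(fit, "methformer")
  expect_identical(names(coef(fit)), colnames(cohort$beta))
  expect_output(print(fit), "methformer fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.methformer")
  expect_output(print(s), "top CpGs")
  expect_length(fitted(fit), nrow(cohort$beta))
  expect_equal(unname(residuals(fit)),
               unname(cohort$samples$diagnosis - fitted(fit)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("predict supports prob, class, and margin types", {
  cohort <- tiny_cohort(seed = 22L)
  fit <- methformer(cohort$beta, cohort$samples, spec_args = tiny_spec_args(),
                    train = fast_train(), seed = 1L)
  pr <- predict(fit, cohort$beta, cohort$samples, type = "prob")
  expect_length(pr, nrow(cohort$beta))
  expect_true(all(pr > 0 & pr < 1))
  cl <- predict(fit, cohort$beta, cohort$samples, type = "class")
  expect_identical(cl, as.integer(pr >= 0.5))
  mg <- predict(fit, cohort$beta, cohort$samples, type = "margin")
  expect_equal(dim(mg), dim(cohort$beta))
  expect_equal(mg[3, ],
               fit$params$proj_w * cohort$beta[3, ] + fit$params$proj_b,
               ignore_attr = TRUE)
  # missing model CpGs are rejected
  expect_error(predict(fit, cohort$beta[, -1], cohort$samples), "missing")
})

test_that("identical seeds give identical fits; feature selection stays in-split", {
  cohort <- tiny_cohort(seed = 23L, n = 30L, P = 80L)
  f1 <- methformer(cohort$beta, cohort$samples, spec_args = tiny_spec_args(),
                   k = 20L, train = fast_train(), seed = 7L)
  f2 <- methformer(cohort$beta, cohort$samples, spec_args = tiny_spec_args(),
                   k = 20L, train = fast_train(), seed = 7L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$split$assignment, f2$split$assignment)
  expect_identical(f1$cpg_ids, f2$cpg_ids)
  # the selected set equals selection computed on the training rows alone
  tr_ids <- names(f1$split$assignment)[f1$split$assignment == "train"]
  rows <- match(tr_ids, cohort$samples$sample_id)
  sel <- select_variable_cpgs(cohort$beta[tr_ids, ], cohort$samples[rows, ], 20L)
  expect_identical(f1$cpg_ids, sel$selected_ids)
})

test_that("checkpoints round-trip through save/load with identical predictions", {
  cohort <- tiny_cohort(seed = 24L)
  fit <- methformer(cohort$beta, cohort$samples, spec_args = tiny_spec_args(),
                    train = fast_train(), seed = 3L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_s3_class(back, "methformer")
  expect_identical(predict(back, cohort$beta, cohort$samples),
                   predict(fit, cohort$beta, cohort$samples))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "schema")
})

test_that("random-search tuning finds the better configuration", {
  objective <- function(p) -(p$x - 2)^2
  space <- list(x = list(type = "float", low = 0, high = 4))
  res <- tune(objective, space, budget = 40L, seed = 1L)
  expect_lt(abs(res$best_params$x - 2), 0.5)
  expect_equal(nrow(res$trials), 40L)
  expect_equal(res$best_value, max(res$trials$value))
  # deterministic per seed
  res2 <- tune(objective, space, budget = 40L, seed = 1L)
  expect_identical(res$best_params, res2$best_params)
  # int and categorical types
  res3 <- tune(function(p) p$n + (p$opt == "b"),
               list(n = list(type = "int", low = 1, high = 3),
                    opt = list(type = "categorical", values = list("a", "b"))),
               budget = 30L, seed = 2L)
  expect_equal(res3$best_value, 4)
})

test_that("tuning records failing trials and errors only when all fail", {
  calls <- 0L
  flaky <- function(p) {
    calls <<- calls + 1L
    if (calls %% 2 == 0) stop("boom")
    p$x
  }
  space <- list(x = list(type = "float", low = 0, high = 1))
  res <- tune(flaky, space, budget = 6L, seed = 3L)
  expect_equal(sum(is.na(res$trials$value)), 3L)
  expect_error(tune(function(p) stop("always"), space, budget = 3L, seed = 1L),
               "all tuning trials failed")
  expect_error(tune(function(p) 1, list(), budget = 2L), "empty search space")
})

test_that("a custom tuning engine is honored", {
  engine <- function(search_space, budget, objective, seed) {
    lapply(seq_len(budget), function(i) {
      p <- list(x = i)
      list(params = p, value = objective(p))
    })
  }
  res <- tune(function(p) -abs(p$x - 3), list(x = list(type = "float", low = 0, high = 5)),
              budget = 5L, engine = engine, seed = 1L)
  expect_equal(res$best_params$x, 3)
})
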