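# Metrics, the multi-seed repetition protocol, and the Welch's t-test
# baseline comparison harness.

# Midrank (Mann-Whitney) AUC: ties contribute 1/2 via midranks.
auc_midrank <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics: AUC, accuracy, F1
#'
#' AUC uses the rank (Mann-Whitney) formulation with midranks for ties;
#' accuracy and F1 (positive class = case, label 1) are computed at the given
#' probability threshold.
#'
#' @param y_true 0/1 labels.
#' @param scores Class-1 probabilities (any monotone score works for AUC).
#' @param threshold Classification threshold on the score (default 0.5).
#' @return Named list `auc`, `acc`, `f1`. If only one class is present the AUC
#'   is `NA` with a warning; accuracy and F1 are still returned.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores) || length(y_true) == 0) {
    stop("y_true and scores must be non-empty and equal length", call. = FALSE)
  }
  auc <- auc_midrank(y_true, scores)
  if (is.na(auc)) warning("AUC undefined: only one class present in y_true")
  pred <- as.integer(scores >= threshold)
  acc <- mean(pred == y_true)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auc = auc, acc = acc, f1 = f1)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both samples have zero variance: p = 1 if
#' the means are equal, otherwise t is infinite and p = 0.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return List with `t`, `p`, `df`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    return(list(t = sign(ma - mb) * Inf, p = 0, df = length(a) + length(b) - 2))
  }
  se2a <- va / length(a); se2b <- vb / length(b)
  t <- (ma - mb) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Small deterministic content hash (FNV-1a over serialized bytes) used to
# assert that every model in a benchmark saw the identical split. The 32-bit
# state lives in a double, so the xor and the modular multiply are done on
# 16-bit halves (doubles hold every intermediate exactly).
split_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", (h - lo) / 65536, lo)
}

#' Pipeline configuration for multi-seed experiments
#'
#' Bundles the synthetic cohort settings with feature selection, split
#' fractions, architecture, and training/loss settings.
#'
#' @param synth A [synth_config()] (the data-generating conditions).
#' @param k Per-tissue feature-selection size; `NULL` trains on all sites.
#' @param fractions Train/val/test fractions.
#' @param spec_args Named list of [model_spec()] overrides (P and n_tissues
#'   are filled from the data).
#' @param train A [train_config()].
#' @param loss A [loss_config()].
#' @return Object of class `methformer_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), k = NULL,
                            fractions = c(0.8, 0.1, 0.1), spec_args = list(),
                            train = train_config(), loss = loss_config()) {
  structure(list(synth = synth, k = k, fractions = fractions,
                 spec_args = spec_args, train = train, loss = loss),
            class = "methformer_pipeline_config")
}

run_single_seed <- function(cohort, cfg, seed, return_model = FALSE) {
  fit <- methformer(
    cohort$beta, cohort$samples,
    spec_args = cfg$spec_args, k = cfg$k, fractions = cfg$fractions,
    train = cfg$train, loss = cfg$loss, seed = seed, verbose = FALSE
  )
  test_ids <- names(fit$split$assignment)[fit$split$assignment == "test"]
  idx <- match(test_ids, cohort$samples$sample_id)
  scores <- predict(fit, cohort$beta[test_ids, , drop = FALSE],
                    cohort$samples[idx, , drop = FALSE], type = "prob")
  m <- compute_metrics(cohort$samples$diagnosis[idx], scores)
  out <- list(metrics = m, split = fit$split, scores = scores,
              y_test = cohort$samples$diagnosis[idx])
  if (return_model) out$model <- fit
  out
}

#' Repeat the full split/train/test cycle over random seeds
#'
#' Each seed controls the stratified split, weight initialization, batch
#' shuffling, and dropout; the cohort itself is fixed by the pipeline config.
#' Per-seed failures are recorded and the run continues.
#'
#' @param cfg A [pipeline_config()].
#' @param seeds Integer vector of seeds (length >= 1).
#' @param cohort Optional pre-generated cohort (list with `beta`, `samples`);
#'   by default generated from `cfg$synth`.
#' @return Object of class `methformer_metrics_report`: `per_seed` data frame
#'   (seed, auc, acc, f1), `mean` and `sd` per metric (sd with n-1
#'   denominator, reported only when >= 2 seeds succeeded), `n_seeds`, and
#'   `failures`.
#' @export
multiseed_run <- function(cfg, seeds, cohort = NULL) {
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  if (is.null(cohort)) cohort <- generate_cohort(cfg$synth)
  rows <- list(); failures <- list()
  for (s in seeds) {
    res <- tryCatch(run_single_seed(cohort, cfg, s), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(s)]] <- conditionMessage(res)
      rows[[as.character(s)]] <- data.frame(seed = s, auc = NA_real_,
                                            acc = NA_real_, f1 = NA_real_)
    } else {
      rows[[as.character(s)]] <- data.frame(seed = s, auc = res$metrics$auc,
                                            acc = res$metrics$acc, f1 = res$metrics$f1)
    }
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  ok <- stats::complete.cases(per_seed)
  agg <- function(f) vapply(per_seed[ok, c("auc", "acc", "f1")], f, numeric(1))
  structure(list(
    per_seed = per_seed,
    mean = agg(mean),
    sd = if (sum(ok) >= 2) agg(stats::sd) else NULL,
    n_seeds = length(seeds),
    failures = failures
  ), class = "methformer_metrics_report")
}

#' @export
print.methformer_metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d seeds:\n", x$n_seeds))
  for (m in c("auc", "acc", "f1")) {
    cat(sprintf("  %s: %.3f%s\n", m, x$mean[[m]],
                if (!is.null(x$sd)) sprintf(" +/- %.3f", x$sd[[m]]) else ""))
  }
  if (length(x$failures) > 0) {
    cat("  failed seeds:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

# --- baseline registry ----------------------------------------------------------

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this baseline", call. = FALSE)
  }
}

#' Baseline classifier registry
#'
#' Standard classifiers (probabilistic, linear, and nonlinear ensembles) that
#' consume the same flattened feature table (selected beta values + encoded
#' covariates + one-hot tissue block). Each entry is a list with `fit(x, y)`
#' and `score(model, x)` returning class-1 scores.
#'
#' @return Named list of baseline definitions.
#' @export
baseline_registry <- function() {
  list(
    gaussian_nb = list(fit = function(x, y) {
      need_pkg("e1071")
      e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
    }, score = function(m, x) stats::predict(m, x, type = "raw")[, "1"]),
    logistic_l2 = list(fit = function(x, y) {
      need_pkg("glmnet")
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 0.01)
    }, score = function(m, x) as.numeric(stats::predict(m, x, type = "response"))),
    lda = list(fit = function(x, y) {
      need_pkg("MASS")
      # drop constant columns; LDA tolerates collinearity with a warning
      keep <- apply(x, 2, stats::sd) > 0
      m <- suppressWarnings(MASS::lda(x[, keep, drop = FALSE], grouping = factor(y)))
      list(m = m, keep = keep)
    }, score = function(m, x) {
      as.numeric(stats::predict(m$m, x[, m$keep, drop = FALSE])$posterior[, "1"])
    }),
    svm_linear = list(fit = function(x, y) {
      need_pkg("e1071")
      m <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear", scale = FALSE)
      dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1]
      flip <- !is.na(auc_midrank(y, dv)) && auc_midrank(y, dv) < 0.5
      list(m = m, flip = flip)
    }, score = function(m, x) {
      dv <- attr(stats::predict(m$m, x, decision.values = TRUE), "decision.values")[, 1]
      s <- if (m$flip) -dv else dv
      1 / (1 + exp(-s))  # squash decision values to (0,1) for thresholding
    }),
    random_forest = list(fit = function(x, y) {
      need_pkg("randomForest")
      randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 200)
    }, score = function(m, x) stats::predict(m, x, type = "prob")[, "1"]),
    gradient_boosting = list(fit = function(x, y) {
      need_pkg("xgboost")
      xgboost::xgboost(data = x, label = y, nrounds = 50, verbose = 0,
                       params = list(objective = "binary:logistic",
                                     max_depth = 3, eta = 0.3, nthread = 1))
    }, score = function(m, x) stats::predict(m, x)),
    mlp = list(fit = function(x, y) {
      need_pkg("nnet")
      nnet::nnet(x, y, size = 8, decay = 1e-3, maxit = 200,
                 entropy = TRUE, trace = FALSE, MaxNWts = 1e6)
    }, score = function(m, x) as.numeric(stats::predict(m, x)))
  )
}

# Flattened feature table for baseline models: selected beta columns, encoded
# covariates, and a one-hot tissue block (baselines have no embedding).
baseline_features <- function(beta, samples, selected_ids, age_stats, n_tissues) {
  enc <- encode_covariates(samples, age_stats)
  tis <- matrix(0, nrow(samples), n_tissues,
                dimnames = list(NULL, paste0("tissue", seq_len(n_tissues) - 1L)))
  tis[cbind(seq_len(nrow(samples)), samples$tissue + 1L)] <- 1
  x <- cbind(beta[samples$sample_id, selected_ids, drop = FALSE], enc$covariates, tis)
  storage.mode(x) <- "double"
  x
}

#' Benchmark against baseline classifiers
#'
#' Runs the full per-seed cycle for the conv-transformer and every requested
#' baseline on identical splits and the identical selected-CpG + covariate
#' feature table, then compares each baseline to the reference per metric with
#' Welch's t-test over seeds.
#'
#' @param cfg A [pipeline_config()].
#' @param baseline_names Names from [baseline_registry()].
#' @param seeds Integer seeds (>= 2 for the t-tests).
#' @param cohort Optional pre-generated cohort.
#' @return Data frame with columns model, metric, mean, sd, t, p (reference
#'   rows carry NA t/p), plus attribute `per_seed` with all raw values.
#' @export
benchmark <- function(cfg, baseline_names, seeds, cohort = NULL) {
  registry <- baseline_registry()
  unknown <- setdiff(baseline_names, names(registry))
  if (length(unknown) > 0) {
    stop("unknown baseline(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(registry), collapse = ", "), call. = FALSE)
  }
  if (is.null(cohort)) cohort <- generate_cohort(cfg$synth)
  models <- c("methformer", baseline_names)
  per_seed <- list()
  split_hashes <- character(0)
  for (s in seeds) {
    ref <- run_single_seed(cohort, cfg, s, return_model = TRUE)
    split <- ref$model$split
    split_hashes <- c(split_hashes, split_hash(split$assignment))
    sel_ids <- ref$model$cpg_ids
    asg <- split$assignment
    tr_ids <- names(asg)[asg != "test"]   # baselines have no early stopping:
    te_ids <- names(asg)[asg == "test"]   # train on train+val, score on test
    tr_rows <- match(tr_ids, cohort$samples$sample_id)
    te_rows <- match(te_ids, cohort$samples$sample_id)
    n_tis <- max(cohort$samples$tissue) + 1L
    x_tr <- baseline_features(cohort$beta, cohort$samples[tr_rows, ], sel_ids,
                              ref$model$age_stats, n_tis)
    x_te <- baseline_features(cohort$beta, cohort$samples[te_rows, ], sel_ids,
                              ref$model$age_stats, n_tis)
    y_tr <- cohort$samples$diagnosis[tr_rows]
    y_te <- cohort$samples$diagnosis[te_rows]
    res_rows <- list(data.frame(seed = s, model = "methformer",
                                auc = ref$metrics$auc, acc = ref$metrics$acc,
                                f1 = ref$metrics$f1))
    for (bn in baseline_names) {
      entry <- registry[[bn]]
      m <- with_seed(derive_seed(s, "misc"), entry$fit(x_tr, y_tr))
      sc <- entry$score(m, x_te)
      mm <- compute_metrics(y_te, sc)
      res_rows[[length(res_rows) + 1]] <-
        data.frame(seed = s, model = bn, auc = mm$auc, acc = mm$acc, f1 = mm$f1)
    }
    per_seed[[as.character(s)]] <- do.call(rbind, res_rows)
  }
  per_seed <- do.call(rbind, per_seed)
  rownames(per_seed) <- NULL
  out <- list()
  for (mod in models) {
    for (met in c("auc", "acc", "f1")) {
      vals <- per_seed[per_seed$model == mod, met]
      ref_vals <- per_seed[per_seed$model == "methformer", met]
      if (mod == "methformer" || length(seeds) < 2) {
        tt <- list(t = NA_real_, p = NA_real_)
      } else {
        tt <- welch_test(vals, ref_vals)
      }
      out[[length(out) + 1]] <- data.frame(
        model = mod, metric = met, mean = mean(vals),
        sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
        t = tt$t, p = tt$p
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "per_seed") <- per_seed
  attr(res, "split_hashes") <- split_hashes
  res
}
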