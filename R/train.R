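# Model fitting: AdamW-style optimizer with decoupled, group-specific weight
# decay (projection layer vs rest), early stopping on validation AUC, and the
# user-facing `methformer()` fit function with its S3 methods.

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay_projection Decoupled weight decay applied to the CpG
#'   projection weights.
#' @param weight_decay_rest Decoupled weight decay applied to the dense weight
#'   matrices of the rest of the network (biases, layer norms, and the tissue
#'   embedding are exempt).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs without validation-AUC
#'   improvement.
#' @param seed Master seed; fans out to initialization, shuffling, and dropout
#'   streams.
#' @return Object of class `methformer_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay_projection = 1e-5,
                         weight_decay_rest = 1e-4, batch_size = 32L,
                         max_epochs = 30L, patience = 10L, seed = 1L) {
  check_scalar(learning_rate, "learning_rate", "numeric", lower = 0)
  check_scalar(weight_decay_projection, "weight_decay_projection", "numeric", lower = 0)
  check_scalar(weight_decay_rest, "weight_decay_rest", "numeric", lower = 0)
  check_scalar(batch_size, "batch_size", "integer", lower = 1)
  check_scalar(max_epochs, "max_epochs", "integer", lower = 1)
  check_scalar(patience, "patience", "integer", lower = 1)
  check_scalar(seed, "seed", "integer")
  structure(list(learning_rate = learning_rate,
                 weight_decay_projection = weight_decay_projection,
                 weight_decay_rest = weight_decay_rest,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "methformer_train_config")
}

# Weight decay group per parameter: "projection" for proj_w, "rest" for dense
# weight matrices, none for biases / layer norms / embeddings.
decay_rate <- function(name, cfg) {
  if (name == "proj_w") return(cfg$weight_decay_projection)
  if (grepl("(_W[qkvo12]?$)|(_W$)|(^head_W$)|(^cov_W$)", name)) return(cfg$weight_decay_rest)
  0
}

adamw_step <- function(params, grads, state, cfg, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  lr <- cfg$learning_rate
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + decay_rate(nm, cfg) * params[[nm]])
  }
  list(params = params, state = state)
}

# Chunked evaluation-mode forward, returning class-1 probabilities.
predict_scores <- function(params, spec, X, Z, tissue, chunk = 128L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    fw <- model_forward(params, spec, X[idx, , drop = FALSE],
                        Z[idx, , drop = FALSE], tissue[idx], training = FALSE)
    out[idx] <- fw$probs[, 2]
  }
  out
}

#' Train a model on prepared splits
#'
#' Optimizes the label-smoothed cross-entropy + top-k margin objective with
#' Adam and decoupled weight decay in two parameter groups (projection vs
#' rest). After every epoch the validation AUC is computed; training stops
#' early when it fails to improve for `patience` epochs, and the checkpoint
#' with the best validation AUC is returned.
#'
#' @param params Initial parameters ([init_params()]).
#' @param spec A [model_spec()].
#' @param data List with elements `train` and `val`, each a list of `X`
#'   (beta matrix), `Z` (covariates), `tissue`, `y` (0/1 labels).
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `params` (best checkpoint), `history` (epoch, train_loss,
#'   val_auc), `best_epoch`, `best_val_auc`.
#' @export
train_model <- function(params, spec, data, train_cfg, loss_cfg, verbose = FALSE) {
  # the margin penalty cannot select more sites than the model sees
  loss_cfg$top_k <- min(loss_cfg$top_k, spec$P)
  tr <- data$train; va <- data$val
  n <- nrow(tr$X)
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_auc = numeric(0))
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  t_step <- 0L
  since_improve <- 0L
  with_seed(derive_seed(train_cfg$seed, "dropout"), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(n, start + train_cfg$batch_size - 1L)]
        fw <- model_forward(params, spec, tr$X[idx, , drop = FALSE],
                            tr$Z[idx, , drop = FALSE], tr$tissue[idx],
                            training = TRUE, keep_cache = TRUE)
        loss <- total_loss(tr$y[idx], fw$probs, fw$margins, loss_cfg)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch starting at %d",
                       epoch, start), call. = FALSE)
        }
        lg <- total_loss_grads(tr$y[idx], fw$probs, fw$margins, loss_cfg)
        bk <- model_backward(params, spec, fw$cache, lg$dlogits, lg$dmargins)
        t_step <- t_step + 1L
        upd <- adamw_step(params, bk$grads, state, train_cfg, t_step)
        params <- upd$params; state <- upd$state
        losses <- c(losses, loss)
      }
      val_scores <- predict_scores(params, spec, va$X, va$Z, va$tissue)
      val_auc <- auc_midrank(va$y, val_scores)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_auc = val_auc))
      msg_verbose(verbose, "epoch %d: train loss %.4f, val AUC %.4f",
                  epoch, mean(losses), val_auc)
      if (!is.na(val_auc) && val_auc > best_auc) {
        best_auc <- val_auc; best_params <- params; best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= train_cfg$patience) break
      }
    }
  })
  list(params = best_params, history = history,
       best_epoch = best_epoch, best_val_auc = best_auc)
}

#' Fit a convolution-transformer methylation classifier
#'
#' The main fitting function: takes a beta-value matrix and a sample table,
#' performs the stratified split, optional per-tissue variance feature
#' selection (on training samples only), covariate encoding with
#' training-set age statistics, and trains the model with early stopping on
#' validation AUC.
#'
#' @param beta Samples x CpGs beta matrix (values in `[0,1]`, dimnames set).
#' @param samples Sample table (sample_id, diagnosis, age, sex, tissue, ...).
#' @param spec_args Named list of [model_spec()] overrides.
#' @param k Per-tissue feature-selection size; `NULL` uses all CpGs.
#' @param fractions Train/val/test fractions for the stratified split.
#' @param split Optional precomputed [stratified_split()]; overrides
#'   `fractions`.
#' @param train A [train_config()] (its seed is overridden by `seed`).
#' @param loss A [loss_config()]; its `top_k` is clamped to the number of
#'   modeled sites.
#' @param seed Master seed controlling split, initialization, shuffling, and
#'   dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `methformer` with methods `print`, `summary`,
#'   `coef` (signed per-CpG projection weights), `predict`, `plot`,
#'   `fitted`, and `residuals`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_samples_per_tissue = 40, n_cpgs = 120,
#'                                        n_causal = 10, seed = 3))
#' fit <- methformer(cohort$beta, cohort$samples,
#'                   spec_args = list(pools = c(2, 2), conv_channels = c(4, 8),
#'                                    n_heads = 2),
#'                   train = train_config(max_epochs = 2), seed = 1)
#' head(coef(fit))
#' @export
methformer <- function(beta, samples, spec_args = list(), k = NULL,
                       fractions = c(0.8, 0.1, 0.1), split = NULL,
                       train = train_config(), loss = loss_config(),
                       seed = 1L, verbose = FALSE) {
  validate_beta_matrix(beta)
  validate_sample_table(samples, beta)
  check_scalar(seed, "seed", "integer")
  if (is.null(split)) split <- stratified_split(samples, fractions, seed)
  asg <- split$assignment[samples$sample_id]
  if (anyNA(asg)) stop("split assignment does not cover all samples", call. = FALSE)
  train_rows <- which(asg == "train")
  val_rows <- which(asg == "val")
  # feature selection on training samples only (no leakage into val/test)
  if (!is.null(k)) {
    sel <- select_variable_cpgs(beta[samples$sample_id[train_rows], , drop = FALSE],
                                samples[train_rows, , drop = FALSE], k)
    cpg_ids <- sel$selected_ids
  } else {
    cpg_ids <- colnames(beta)
  }
  enc_train <- encode_covariates(samples[train_rows, , drop = FALSE])
  age_stats <- enc_train$age_stats
  enc_val <- encode_covariates(samples[val_rows, , drop = FALSE], age_stats)
  n_tissues <- max(samples$tissue) + 1L
  spec <- do.call(model_spec, utils::modifyList(
    list(P = length(cpg_ids), n_tissues = n_tissues), spec_args))
  params <- init_params(spec, seed)
  train_cfg <- train
  train_cfg$seed <- as.integer(seed)
  # the margin penalty cannot select more sites than the model sees
  loss$top_k <- min(loss$top_k, spec$P)
  data <- list(
    train = list(X = beta[samples$sample_id[train_rows], cpg_ids, drop = FALSE],
                 Z = enc_train$covariates, tissue = enc_train$tissue,
                 y = samples$diagnosis[train_rows]),
    val = list(X = beta[samples$sample_id[val_rows], cpg_ids, drop = FALSE],
               Z = enc_val$covariates, tissue = enc_val$tissue,
               y = samples$diagnosis[val_rows])
  )
  res <- train_model(params, spec, data, train_cfg, loss, verbose = verbose)
  obj <- structure(list(
    params = res$params, spec = spec, cpg_ids = cpg_ids,
    age_stats = age_stats, split = split, history = res$history,
    best_epoch = res$best_epoch, best_val_auc = res$best_val_auc,
    train_cfg = train_cfg, loss_cfg = loss, seed = as.integer(seed),
    call = match.call()
  ), class = "methformer")
  # fitted class-1 probabilities on the full cohort (for residuals/summary)
  obj$fitted_values <- stats::setNames(
    predict(obj, beta, samples, type = "prob"), samples$sample_id)
  obj$y <- stats::setNames(samples$diagnosis, samples$sample_id)
  obj
}

prepare_newdata <- function(object, beta, samples) {
  validate_sample_table(samples, beta)
  missing <- setdiff(object$cpg_ids, colnames(beta))
  if (length(missing) > 0) {
    stop("newdata is missing ", length(missing), " model CpGs (e.g. ",
         missing[1], ")", call. = FALSE)
  }
  enc <- encode_covariates(samples, object$age_stats)
  if (any(enc$tissue < 0 | enc$tissue >= object$spec$n_tissues)) {
    stop("unseen tissue code in newdata", call. = FALSE)
  }
  list(X = beta[samples$sample_id, object$cpg_ids, drop = FALSE],
       Z = enc$covariates, tissue = enc$tissue)
}

#' Predict from a fitted model
#'
#' @param object A fitted [methformer()] model.
#' @param beta Beta matrix containing at least the model's CpG columns.
#' @param samples Matching sample table.
#' @param type `"prob"` (class-1 probability), `"class"` (0/1 at threshold
#'   0.5), or `"margin"` (the per-CpG margin map, samples x P).
#' @param ... Unused.
#' @export
predict.methformer <- function(object, beta, samples,
                               type = c("prob", "class", "margin"), ...) {
  type <- match.arg(type)
  nd <- prepare_newdata(object, beta, samples)
  if (type == "margin") {
    return(cpg_project(nd$X, object$params$proj_w, object$params$proj_b))
  }
  scores <- predict_scores(object$params, object$spec, nd$X, nd$Z, nd$tissue)
  if (type == "class") as.integer(scores >= 0.5) else scores
}

#' @export
print.methformer <- function(x, ...) {
  cat("methformer fit\n")
  print(x$spec)
  cat(sprintf("  parameters: %d; best val AUC %.3f at epoch %d/%d\n",
              count_params(x$spec), x$best_val_auc, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
summary.methformer <- function(object, ...) {
  w <- stats::setNames(object$params$proj_w, object$cpg_ids)
  out <- list(
    spec = object$spec, n_params = count_params(object$spec),
    history = object$history, best_epoch = object$best_epoch,
    best_val_auc = object$best_val_auc,
    top_sites = utils::head(w[order(-abs(w))], 10),
    split_sizes = table(object$split$assignment)
  )
  class(out) <- "summary.methformer"
  out
}

#' @export
print.summary.methformer <- function(x, ...) {
  print(x$spec)
  cat(sprintf("parameters: %d\nbest validation AUC: %.3f (epoch %d)\n",
              x$n_params, x$best_val_auc, x$best_epoch))
  cat("split sizes:", paste(names(x$split_sizes), x$split_sizes, sep = "=",
                            collapse = " "), "\n")
  cat("top CpGs by |projection weight|:\n")
  print(round(x$top_sites, 4))
  invisible(x)
}

#' @export
coef.methformer <- function(object, ...) {
  stats::setNames(object$params$proj_w, object$cpg_ids)
}

#' @export
fitted.methformer <- function(object, ...) object$fitted_values

#' @export
residuals.methformer <- function(object, ...) {
  object$y - object$fitted_values
}

#' Plot training history
#'
#' Two panels: mean training loss and validation AUC per epoch, with the
#' selected (best-AUC) epoch marked.
#'
#' @param x A fitted [methformer()] model.
#' @param ... Passed to [plot()].
#' @export
plot.methformer <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$history
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch", ylab = "train loss", ...)
  plot(h$epoch, h$val_auc, type = "b", xlab = "epoch", ylab = "validation AUC", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

# --- hyperparameter search -------------------------------------------------------

sample_trial <- function(search_space) {
  out <- list()
  for (nm in names(search_space)) {
    s <- search_space[[nm]]
    out[[nm]] <- switch(s$type,
      float = if (isTRUE(s$log)) exp(stats::runif(1, log(s$low), log(s$high)))
              else stats::runif(1, s$low, s$high),
      int = sample(seq(s$low, s$high), 1),
      categorical = s$values[[sample.int(length(s$values), 1)]],
      stop("unknown search-space type: ", s$type, call. = FALSE)
    )
  }
  out
}

#' Hyperparameter search over a validation-AUC objective
#'
#' The optimization engine is pluggable: the built-in engine is random search;
#' an external engine (e.g. a Bayesian optimizer) can be supplied as a
#' function `engine(search_space, budget, objective, seed)` returning a list
#' of trials `list(params =, value =)`. The best configuration is selected by
#' highest objective value (validation AUC) among completed trials.
#'
#' @param objective Function `params -> numeric` (validation AUC). Failing
#'   trials are recorded and skipped.
#' @param search_space Named list; each entry
#'   `list(type = "float"|"int"|"categorical", low =, high =, log =, values =)`.
#' @param budget Number of trials.
#' @param engine Optional engine function (see Details).
#' @param seed Seed for the sampling stream.
#' @return List with `best_params`, `best_value`, and a `trials` data frame.
#' @export
tune <- function(objective, search_space, budget, engine = NULL, seed = 1L) {
  if (length(search_space) == 0) stop("empty search space", call. = FALSE)
  check_scalar(budget, "budget", "integer", lower = 1)
  if (is.null(engine)) {
    engine <- function(search_space, budget, objective, seed) {
      with_seed(derive_seed(seed, "tune"), {
        lapply(seq_len(budget), function(i) {
          p <- sample_trial(search_space)
          v <- tryCatch(objective(p), error = function(e) NA_real_)
          list(params = p, value = v)
        })
      })
    }
  }
  trials <- engine(search_space, budget, objective, seed)
  values <- vapply(trials, function(t) as.numeric(t$value %||% NA_real_), numeric(1))
  if (all(is.na(values))) stop("all tuning trials failed", call. = FALSE)
  best <- which.max(values)
  list(
    best_params = trials[[best]]$params,
    best_value = values[best],
    trials = data.frame(trial = seq_along(values), value = values)
  )
}
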