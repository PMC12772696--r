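# Multi-resolution interpretability: signed per-CpG linear weights,
# Grad-CAM++ over convolutional feature maps, exact and permutation-sampled
# Shapley attributions with background substitution, and attention maps with
# row entropies.

#' Per-CpG linear projection importance
#'
#' The projection weights act like per-site regression coefficients: signed
#' values give direction, magnitudes give importance. They are a property of
#' the projection layer alone, invariant to anything downstream.
#'
#' @param model A fitted [methformer()] model (or a list with `params`,
#'   `cpg_ids`).
#' @return List with `signed` (named weights) and `magnitudes` (a saliency
#'   curve of `|w|`, class `methformer_saliency`).
#' @export
linear_importance <- function(model) {
  w <- stats::setNames(model$params$proj_w, model$cpg_ids)
  list(signed = w,
       magnitudes = structure(list(values = abs(w), source = "linear",
                                   class_index = NA_integer_),
                              class = "methformer_saliency"))
}

#' Permutation test for rank enrichment of a site set
#'
#' Tests whether the mean rank of `values` at `idx` exceeds what random site
#' sets of the same size achieve (one-sided).
#'
#' @param values Numeric vector (e.g. `|projection weights|`).
#' @param idx Indices of the candidate (e.g. causal) sites.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return List with `statistic` (observed mean rank), `p` (permutation
#'   p-value with the +1 correction).
#' @export
rank_enrichment_test <- function(values, idx, n_perm = 10000L, seed = 1L) {
  r <- rank(values)
  obs <- mean(r[idx])
  with_seed(derive_seed(seed, "misc"), {
    null <- vapply(seq_len(n_perm), function(i) {
      mean(r[sample.int(length(values), length(idx))])
    }, numeric(1))
    list(statistic = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
  })
}

# Grad-CAM++ maps for a batch: returns a B x P matrix of non-negative
# saliency values upsampled to CpG resolution.
gradcam_batch <- function(params, spec, X, Z, tissue, class_index, stage,
                          eps = 1e-8) {
  n_stages <- length(spec$conv_channels)
  if (!(stage %in% seq_len(n_stages))) {
    stop("unknown convolution stage: ", stage, " (model has ", n_stages, ")",
         call. = FALSE)
  }
  if (class_index < 0 || class_index >= spec$n_classes) {
    stop("class_index out of range [0, n_classes)", call. = FALSE)
  }
  fw <- model_forward(params, spec, X, Z, tissue, training = FALSE, keep_cache = TRUE)
  B <- nrow(X)
  dlogits <- matrix(0, B, spec$n_classes)
  dlogits[, class_index + 1L] <- 1
  bk <- model_backward(params, spec, fw$cache, dlogits, conv_grads = TRUE)
  A <- fw$cache$conv$stages[[stage]]$act   # (B, L', C) post-GELU map
  G <- bk$dconv_act[[stage]]               # gradient of the class logit
  # alpha_{k,t} = G^2 / (2 G^2 + sum_u A_u G_u^3 + eps), per channel
  G2 <- G^2
  sumAG3 <- colSums(aperm(A * G^3, c(2, 1, 3)), dims = 1)      # (B, C)
  Lp <- dim(A)[2]
  denomS <- aperm(array(sumAG3, c(B, dim(A)[3], Lp)), c(1, 3, 2))
  alpha <- G2 / (2 * G2 + denomS + eps)
  # channel weights: alpha-weighted sum of ReLU(G) over positions
  w <- colSums(aperm(alpha * pmax(G, 0), c(2, 1, 3)), dims = 1)  # (B, C)
  Warr <- aperm(array(w, c(B, dim(A)[3], Lp)), c(1, 3, 2))
  M <- pmax(colSums(aperm(A * Warr, c(3, 1, 2)), dims = 1), 0)   # (B, L')
  # upsample to CpG resolution via receptive-field centers
  centers <- stage_centers(spec, stage)
  out <- matrix(0, B, spec$P)
  for (b in seq_len(B)) {
    out[b, ] <- if (length(centers) == 1) rep(M[b, 1], spec$P) else
      stats::approx(centers, M[b, ], xout = seq_len(spec$P), rule = 2)$y
  }
  out
}

#' Grad-CAM++ saliency for one sample
#'
#' Computes position-specific alpha weights from the gradients of the class
#' logit with respect to a convolution stage's post-GELU feature map,
#' aggregates them into channel weights, takes the ReLU of the
#' channel-weighted activation map, and upsamples to CpG resolution by
#' piecewise-linear interpolation over the receptive-field centers.
#'
#' @param model A fitted [methformer()] model.
#' @param x Length-P beta vector over the model's CpGs.
#' @param z Covariate vector (age_z, sex) or a one-row sample table via
#'   [predict()]-style preparation is up to the caller.
#' @param r Tissue code (0-based).
#' @param class_index Class whose logit is explained (0-based; 1 = case).
#' @param layer_choice Convolution stage (default: the last, region-level
#'   stage; stage 1 gives fine-grained maps).
#' @return A `methformer_saliency` with non-negative `values` (length P,
#'   named by CpG id).
#' @export
gradcam_pp <- function(model, x, z, r, class_index = 1L,
                       layer_choice = length(model$spec$conv_channels)) {
  map <- gradcam_batch(model$params, model$spec, matrix(x, 1),
                       matrix(z, 1), as.integer(r), class_index, layer_choice)
  structure(list(values = stats::setNames(map[1, ], model$cpg_ids),
                 source = "gradcampp", class_index = as.integer(class_index)),
            class = "methformer_saliency")
}

#' Tissue-wise Grad-CAM++ activation profiles
#'
#' Per-tissue curve = mean of per-sample maps over that tissue's samples. The
#' overall curve averages the per-tissue means (not the samples), so tissues
#' with more samples do not dominate; per-sample averaging is available with
#' `average = "samples"`. Sample counts per tissue are reported alongside.
#'
#' @param model A fitted [methformer()] model.
#' @param beta,samples Cohort beta matrix and sample table.
#' @param class_index Explained class (0-based).
#' @param layer_choice Convolution stage.
#' @param average `"tissues"` (default) or `"samples"` for the overall curve.
#' @param chunk Batch size for the forward/backward sweeps.
#' @return List with `per_tissue` (matrix, tissues x P), `overall` (length P),
#'   `n_per_tissue`.
#' @export
gradcam_tissue_profile <- function(model, beta, samples, class_index = 1L,
                                   layer_choice = length(model$spec$conv_channels),
                                   average = c("tissues", "samples"), chunk = 64L) {
  average <- match.arg(average)
  nd <- prepare_newdata(model, beta, samples)
  tissues <- sort(unique(samples$tissue))
  P <- model$spec$P
  per_tissue <- matrix(NA_real_, length(tissues), P,
                       dimnames = list(as.character(tissues), model$cpg_ids))
  counts <- integer(length(tissues)); names(counts) <- as.character(tissues)
  all_sum <- numeric(P); all_n <- 0L
  for (ti in seq_along(tissues)) {
    rows <- which(samples$tissue == tissues[ti])
    counts[ti] <- length(rows)
    if (length(rows) == 0) {
      warning("tissue ", tissues[ti], " has no samples; excluded")
      next
    }
    acc <- numeric(P)
    for (start in seq(1L, length(rows), by = chunk)) {
      idx <- rows[start:min(length(rows), start + chunk - 1L)]
      maps <- gradcam_batch(model$params, model$spec, nd$X[idx, , drop = FALSE],
                            nd$Z[idx, , drop = FALSE], nd$tissue[idx],
                            class_index, layer_choice)
      acc <- acc + colSums(maps)
    }
    per_tissue[ti, ] <- acc / length(rows)
    all_sum <- all_sum + acc; all_n <- all_n + length(rows)
  }
  ok <- !is.na(per_tissue[, 1])
  overall <- if (average == "tissues") colMeans(per_tissue[ok, , drop = FALSE])
             else all_sum / all_n
  list(per_tissue = per_tissue[ok, , drop = FALSE],
       overall = stats::setNames(overall, model$cpg_ids),
       n_per_tissue = counts)
}

# --- Shapley attributions --------------------------------------------------------

# Normalize the `features` argument: an integer vector means singleton
# features; a list of integer vectors means grouped (window) features.
as_feature_groups <- function(features) {
  if (is.list(features)) lapply(features, as.integer) else as.list(as.integer(features))
}

substitute_features <- function(x, background, groups, included) {
  out <- background
  keep <- unlist(groups[included], use.names = FALSE)
  out[keep] <- x[keep]
  # coordinates outside all groups stay at x's own values
  outside <- setdiff(seq_along(x), unlist(groups, use.names = FALSE))
  out[outside] <- x[outside]
  out
}

#' Exact Shapley attribution by subset enumeration
#'
#' Enumerates all coalitions of the explained features with the combinatorial
#' Shapley weights `w(S) = |S|! (|F|-|S|-1)! / |F|!`. The value function
#' substitutes the coordinates of features outside the coalition with the
#' background sample's values; covariates and tissue are held fixed inside
#' `predict_fn`. Efficiency (`sum(phi) = f(x) - f(background)`) holds within
#' numerical tolerance.
#'
#' @param predict_fn Function taking an (n x P) matrix and returning the
#'   class-c model output per row (covariates/tissue already bound).
#' @param x Length-P input vector.
#' @param background Length-P background (reference) vector.
#' @param features Integer vector of explained feature indices, or a list of
#'   integer vectors for grouped (window) features. At most 14 features.
#' @param class_index Explained class, recorded as metadata.
#' @return Object of class `methformer_shapley`: `phi`, `value_x`,
#'   `value_background`, `features`, `class_index`.
#' @export
shapley_exact <- function(predict_fn, x, background, features, class_index = 1L) {
  groups <- as_feature_groups(features)
  nf <- length(groups)
  if (nf > 14) {
    stop("exact enumeration limited to 14 features; use shapley_sampled()",
         call. = FALSE)
  }
  n_masks <- bitwShiftL(1L, nf)
  masks <- 0:(n_masks - 1L)
  Xs <- matrix(rep(x, n_masks), n_masks, length(x), byrow = TRUE)
  for (m in masks) {
    included <- which(bitwAnd(bitwShiftR(m, 0:(nf - 1L)), 1L) == 1L)
    Xs[m + 1L, ] <- substitute_features(x, background, groups, included)
  }
  vals <- predict_fn(Xs)
  popcount <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(nf - 1L)), 1L)),
                     numeric(1))
  # Shapley weights by coalition size, via log-factorials
  wt <- exp(lfactorial(0:(nf - 1L)) + lfactorial(nf - (0:(nf - 1L)) - 1L) - lfactorial(nf))
  phi <- numeric(nf)
  for (j in seq_len(nf)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- popcount[without + 1L]
    phi[j] <- sum(wt[s + 1L] * (vals[bitwOr(without, bit) + 1L] - vals[without + 1L]))
  }
  structure(list(phi = phi, value_x = vals[n_masks], value_background = vals[1L],
                 features = groups, class_index = as.integer(class_index),
                 method = "exact"),
            class = "methformer_shapley")
}

#' Monte-Carlo Shapley attribution by permutation sampling
#'
#' Unbiased permutation estimate of the Shapley values: for each sampled
#' ordering, features are switched from the background to the explained
#' sample one at a time and the marginal output changes are recorded.
#' Converges to [shapley_exact()] as `n_permutations` grows; a per-feature
#' standard error is reported.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of sampled orderings (>= 1).
#' @param seed Seed; fixed seed gives reproducible output.
#' @param chunk Permutations evaluated per predict_fn call.
#' @return `methformer_shapley` with `phi`, `se`, and `n_permutations`.
#' @export
shapley_sampled <- function(predict_fn, x, background, features, class_index = 1L,
                            n_permutations = 200L, seed = 1L, chunk = 64L) {
  groups <- as_feature_groups(features)
  nf <- length(groups)
  check_scalar(n_permutations, "n_permutations", "integer", lower = 1)
  base <- substitute_features(x, background, groups, integer(0))
  contrib <- matrix(0, n_permutations, nf)
  with_seed(derive_seed(seed, "misc"), {
    done <- 0L
    while (done < n_permutations) {
      nb <- min(chunk, n_permutations - done)
      perms <- lapply(seq_len(nb), function(i) sample.int(nf))
      # rows: for each permutation, the nf+1 states of the walk
      Xs <- matrix(0, nb * (nf + 1L), length(x))
      for (i in seq_len(nb)) {
        cur <- base
        Xs[(i - 1L) * (nf + 1L) + 1L, ] <- cur
        for (step in seq_len(nf)) {
          g <- groups[[perms[[i]][step]]]
          cur[g] <- x[g]
          Xs[(i - 1L) * (nf + 1L) + step + 1L, ] <- cur
        }
      }
      vals <- predict_fn(Xs)
      for (i in seq_len(nb)) {
        v <- vals[((i - 1L) * (nf + 1L) + 1L):(i * (nf + 1L))]
        contrib[done + i, perms[[i]]] <- diff(v)
      }
      done <- done + nb
    }
  })
  phi <- colMeans(contrib)
  se <- if (n_permutations >= 2) {
    apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  } else rep(NA_real_, nf)
  structure(list(phi = phi, se = se, features = groups,
                 class_index = as.integer(class_index),
                 n_permutations = as.integer(n_permutations),
                 method = "sampled"),
            class = "methformer_shapley")
}

#' @export
print.methformer_shapley <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s) over %d features; sum(phi) = %.4f\n",
              x$method, length(x$phi), sum(x$phi)))
  invisible(x)
}

# Bind a fitted model into a class-c prediction function over beta rows, with
# covariates and tissue fixed.
model_predict_fn <- function(model, z, r, class_index = 1L) {
  force(z); force(r)
  function(X) {
    n <- nrow(X)
    Z <- matrix(z, n, length(z), byrow = TRUE)
    fw_probs <- numeric(n)
    chunk <- 256L
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(n, start + chunk - 1L)
      fw <- model_forward(model$params, model$spec, X[idx, , drop = FALSE],
                          Z[idx, , drop = FALSE], rep(as.integer(r), length(idx)))
      fw_probs[idx] <- fw$probs[, class_index + 1L]
    }
    fw_probs
  }
}

# Choose the Shapley background per policy.
choose_background <- function(beta, samples, policy) {
  if (policy %in% samples$sample_id) {
    return(list(x = beta[policy, ], id = policy))
  }
  controls <- samples$sample_id[samples$diagnosis == 0L]
  if (length(controls) == 0) stop("no control samples for the background", call. = FALSE)
  centroid <- colMeans(beta[controls, , drop = FALSE])
  if (policy == "control_mean") return(list(x = centroid, id = "control_mean"))
  if (policy == "nearest_control") {
    d2 <- rowSums(sweep(beta[controls, , drop = FALSE], 2, centroid)^2)
    id <- controls[which.min(d2)]
    return(list(x = beta[id, ], id = id))
  }
  stop("unknown background policy: ", policy, call. = FALSE)
}

#' Cohort-level SHAP profile
#'
#' Computes per-sample Shapley attributions over the full CpG axis with the
#' sampled estimator, grouping contiguous CpGs into windows to keep the game
#' tractable, and returns the cohort mean curve (the classic mean-SHAP
#' overlay against the linear weights).
#'
#' @param model A fitted [methformer()] model.
#' @param beta,samples Cohort data (the background is chosen among these
#'   samples).
#' @param class_index Explained class (0-based).
#' @param background_policy `"nearest_control"` (control sample closest to the
#'   control centroid; default), `"control_mean"`, or a sample id.
#' @param window_size CpGs per feature window (default: ceiling(P/64)).
#' @param n_permutations Permutations per sample for the sampled estimator.
#' @param seed Seed.
#' @return List with `mean_phi` (signed, length P: each window's phi spread
#'   uniformly over its CpGs), `per_sample` (samples x windows), `windows`,
#'   `background_id`.
#' @export
shap_cohort_profile <- function(model, beta, samples, class_index = 1L,
                                background_policy = "nearest_control",
                                window_size = NULL, n_permutations = 32L,
                                seed = 1L) {
  if (nrow(samples) == 0) stop("empty cohort", call. = FALSE)
  nd <- prepare_newdata(model, beta, samples)
  P <- model$spec$P
  if (is.null(window_size)) window_size <- ceiling(P / 64)
  starts <- seq(1L, P, by = window_size)
  windows <- lapply(starts, function(s) s:min(P, s + window_size - 1L))
  bg <- choose_background(nd$X, samples, background_policy)
  per_sample <- matrix(0, nrow(samples), length(windows),
                       dimnames = list(samples$sample_id, NULL))
  for (i in seq_len(nrow(samples))) {
    pf <- model_predict_fn(model, nd$Z[i, ], nd$tissue[i], class_index)
    sh <- shapley_sampled(pf, nd$X[i, ], bg$x, windows, class_index,
                          n_permutations = n_permutations,
                          seed = derive_seed(seed, "misc") + i)
    per_sample[i, ] <- sh$phi
  }
  mean_w <- colMeans(per_sample)
  mean_phi <- numeric(P)
  for (j in seq_along(windows)) {
    mean_phi[windows[[j]]] <- mean_w[j] / length(windows[[j]])
  }
  list(mean_phi = stats::setNames(mean_phi, model$cpg_ids),
       per_sample = per_sample, windows = windows, background_id = bg$id)
}

# --- attention diagnostics -------------------------------------------------------

shannon_entropy_rows <- function(m) {
  apply(m, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Final-block attention maps and entropies
#'
#' Runs the model in evaluation mode for one sample, extracts the final
#' transformer block's per-head attention matrices, their arithmetic mean,
#' and the Shannon entropy (natural log) of each row of the averaged map.
#' Tissue information enters only at the classifier head, so the maps are
#' identical across tissue codes for the same methylation profile.
#'
#' @param model A fitted [methformer()] model.
#' @param x Length-P beta vector.
#' @param z Covariate vector.
#' @param r Tissue code (0-based).
#' @return Object of class `methformer_attention`: `per_head` (list of H
#'   L x L row-stochastic matrices), `averaged`, `row_entropies`.
#' @export
attention_analysis <- function(model, x, z, r) {
  fw <- model_forward(model$params, model$spec, matrix(x, 1),
                      matrix(z, 1), as.integer(r))
  heads <- fw$attention[[1]]
  averaged <- Reduce(`+`, heads) / length(heads)
  structure(list(per_head = heads, averaged = averaged,
                 row_entropies = shannon_entropy_rows(averaged)),
            class = "methformer_attention")
}

#' @export
print.methformer_attention <- function(x, ...) {
  cat(sprintf("attention bundle: %d heads, %d tokens; mean row entropy %.3f (max %.3f)\n",
              length(x$per_head), nrow(x$averaged),
              mean(x$row_entropies), log(nrow(x$averaged))))
  invisible(x)
}

#' Export an attribution table as TSV
#'
#' Columns: cpg_id, signed_linear_weight, abs_linear_weight, and optionally
#' gradcampp and mean_shap curves on the same CpG index.
#'
#' @param model A fitted [methformer()] model.
#' @param path Output file.
#' @param gradcampp,mean_shap Optional length-P curves.
#' @export
write_attributions <- function(model, path, gradcampp = NULL, mean_shap = NULL) {
  li <- linear_importance(model)
  df <- data.frame(cpg_id = model$cpg_ids,
                   signed_linear_weight = unname(li$signed),
                   abs_linear_weight = unname(li$magnitudes$values))
  if (!is.null(gradcampp)) df$gradcampp <- unname(gradcampp)
  if (!is.null(mean_shap)) df$mean_shap <- unname(mean_shap)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
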