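# Training objective: label-smoothed cross-entropy plus a top-k hinge margin
# regularizer on the CpG-wise margin map.

#' Loss configuration
#'
#' @param epsilon Label smoothing factor in `[0,1)`.
#' @param alpha Weight of the margin regularizer (>= 0).
#' @param top_k Number of hardest CpG sites entering the margin penalty.
#' @param n_classes Number of classes C.
#' @return Object of class `methformer_loss_config`.
#' @export
loss_config <- function(epsilon = 0.05, alpha = 0.1, top_k = 64L, n_classes = 2L) {
  check_scalar(epsilon, "epsilon", "numeric", lower = 0, upper = 1, upper_open = TRUE)
  check_scalar(alpha, "alpha", "numeric", lower = 0)
  check_scalar(top_k, "top_k", "integer", lower = 1)
  check_scalar(n_classes, "n_classes", "integer", lower = 2)
  structure(list(epsilon = epsilon, alpha = alpha, top_k = as.integer(top_k),
                 n_classes = as.integer(n_classes)),
            class = "methformer_loss_config")
}

#' Label smoothing
#'
#' The true class receives `1 - epsilon + epsilon/C`, every other class
#' `epsilon/C`; the entries sum to 1 exactly. With `epsilon = 0` the target is
#' the standard one-hot encoding.
#'
#' @param y Class index (0-based) or vector of indices.
#' @param C Number of classes.
#' @param epsilon Smoothing factor in `[0,1)`.
#' @return Length-C vector, or a matrix with one row per element of `y`.
#' @export
smooth_labels <- function(y, C, epsilon) {
  check_scalar(epsilon, "epsilon", "numeric", lower = 0, upper = 1, upper_open = TRUE)
  check_scalar(C, "C", "integer", lower = 2)
  y <- as.integer(y)
  if (any(y < 0 | y >= C)) stop("class index out of range [0, C)", call. = FALSE)
  out <- matrix(epsilon / C, length(y), C)
  out[cbind(seq_along(y), y + 1L)] <- 1 - epsilon + epsilon / C
  if (length(y) == 1) drop(out) else out
}

#' Cross-entropy between smoothed targets and predicted probabilities
#'
#' `-sum_c target_c * log(prob_c)`, with probabilities floored at 1e-12 before
#' the logarithm (a warning is emitted if the floor is hit at a class with
#' nonzero target mass).
#'
#' @param target Length-C target vector (rows of [smooth_labels()]).
#' @param probs Length-C probability vector.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(target, probs) {
  if (length(target) != length(probs)) stop("target/probs length mismatch", call. = FALSE)
  if (any(probs <= 0 & target > 0)) {
    warning("probability clamped at 1e-12 for a class with nonzero target mass")
  }
  -sum(target * log(pmax(probs, 1e-12)))
}

# Indices of the top_k largest hinge residuals; ties at the k-th position are
# broken by lower CpG index.
topk_hinge_indices <- function(resid, top_k) {
  order(-resid, seq_along(resid))[seq_len(top_k)]
}

#' Top-k hinge margin regularizer
#'
#' Residuals `r_t = max(0, 1 - y_pm * m_t)` are computed per CpG site and the
#' mean of the `top_k` largest is returned ("hard-site" selection). The label
#' is the +/-1 encoding `y_pm = 2y - 1`.
#'
#' @param y_pm Label in `{-1, +1}`.
#' @param m Length-P margin map.
#' @param top_k Number of hardest sites (1 <= top_k <= P).
#' @return Non-negative scalar.
#' @export
margin_regularizer <- function(y_pm, m, top_k) {
  if (!y_pm %in% c(-1, 1)) stop("y_pm must be -1 or +1", call. = FALSE)
  check_scalar(top_k, "top_k", "integer", lower = 1)
  if (top_k > length(m)) stop("top_k exceeds the number of CpG sites", call. = FALSE)
  resid <- pmax(0, 1 - y_pm * m)
  mean(resid[topk_hinge_indices(resid, top_k)])
}

# Gradient of the margin regularizer with respect to the margin map: -y/k at
# the selected sites with positive residual, zero elsewhere (sites outside the
# top-k set or with margin beyond 1 receive no gradient).
margin_regularizer_grad <- function(y_pm, m, top_k) {
  resid <- pmax(0, 1 - y_pm * m)
  idx <- topk_hinge_indices(resid, top_k)
  gr <- numeric(length(m))
  active <- idx[resid[idx] > 0]
  gr[active] <- -y_pm / top_k
  gr
}

#' Total training loss over a batch
#'
#' Mean over samples of label-smoothed cross-entropy plus `alpha` times the
#' top-k hinge margin penalty. With `alpha = 0` this reduces exactly to the
#' mean smoothed cross-entropy.
#'
#' @param y Integer class labels (0-based), length B.
#' @param probs B x C predicted probabilities.
#' @param margins B x P margin maps.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
total_loss <- function(y, probs, margins, cfg) {
  B <- length(y)
  if (B == 0) stop("empty batch", call. = FALSE)
  targets <- smooth_labels(y, cfg$n_classes, cfg$epsilon)
  if (B == 1) targets <- matrix(targets, 1)
  ce <- -rowSums(targets * log(pmax(probs, 1e-12)))
  if (cfg$alpha == 0) return(mean(ce))
  y_pm <- 2 * y - 1
  rm_ <- vapply(seq_len(B), function(i) {
    margin_regularizer(y_pm[i], margins[i, ], cfg$top_k)
  }, numeric(1))
  mean(ce + cfg$alpha * rm_)
}

# Gradients of the batch loss at the logits and at the margin map (for the
# backward pass). Softmax + cross-entropy collapse to (probs - target) / B.
total_loss_grads <- function(y, probs, margins, cfg) {
  B <- length(y)
  targets <- smooth_labels(y, cfg$n_classes, cfg$epsilon)
  if (B == 1) targets <- matrix(targets, 1)
  dlogits <- (probs - targets) / B
  dmargins <- NULL
  if (cfg$alpha > 0) {
    y_pm <- 2 * y - 1
    dmargins <- matrix(0, B, ncol(margins))
    for (i in seq_len(B)) {
      dmargins[i, ] <- cfg$alpha / B *
        margin_regularizer_grad(y_pm[i], margins[i, ], cfg$top_k)
    }
  }
  list(dlogits = dlogits, dmargins = dmargins)
}
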