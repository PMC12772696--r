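# Cohort merging, per-tissue variance feature selection, covariate encoding,
# and stratified splits.

#' Intersect CpG probe sets across cohorts and merge samples
#'
#' Aligns a list of beta matrices to the common probe set (the intersection of
#' their CpG ids, ordered lexicographically) and stacks all samples; the
#' paired sample tables are concatenated with a `cohort` field recording
#' origin.
#'
#' @param matrices List of beta matrices (samples x CpGs with dimnames).
#' @param tables List of matching sample tables (same order and row counts).
#' @return List with elements `beta` and `samples`.
#' @export
intersect_and_merge <- function(matrices, tables) {
  if (length(matrices) < 1) stop("need at least one beta matrix", call. = FALSE)
  if (length(matrices) != length(tables)) {
    stop("matrices and tables must have the same length", call. = FALSE)
  }
  lapply(matrices, validate_beta_matrix)
  ids <- lapply(matrices, colnames)
  if (any(vapply(ids, length, 1L) == 0)) stop("a beta matrix has no CpGs", call. = FALSE)
  common <- Reduce(intersect, ids)
  if (length(common) == 0) {
    # report the pair of batches with the smallest pairwise overlap
    k <- length(ids)
    best <- c(1L, 2L); best_n <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      ov <- length(intersect(ids[[i]], ids[[j]]))
      if (ov < best_n) { best_n <- ov; best <- c(i, j) }
    }
    stop(sprintf(
      "empty CpG intersection across batches; smallest pairwise overlap is between batch %d and batch %d (%d shared probes)",
      best[1], best[2], best_n
    ), call. = FALSE)
  }
  common <- sort(common)
  beta <- do.call(rbind, lapply(matrices, function(m) m[, common, drop = FALSE]))
  samples <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    if (is.null(tab$cohort)) tab$cohort <- paste0("batch", i)
    tab
  }))
  rownames(samples) <- NULL
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id across cohorts: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  validate_sample_table(samples, beta)
  list(beta = beta, samples = samples)
}

# Column variances with the unbiased (n-1) estimator; NA entries are
# mean-imputed within the group first (count reported via message).
col_vars_imputed <- function(x, label = NULL) {
  n_na <- sum(is.na(x))
  if (n_na > 0) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
    message(sprintf("mean-imputed %d missing beta entries%s", n_na,
                    if (is.null(label)) "" else paste0(" in tissue ", label)))
  }
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Select the most variable CpGs within each tissue
#'
#' Computes the per-tissue sample variance of every CpG and keeps, per tissue,
#' the `k` most variable sites (ties broken by CpG id, ascending). The
#' modeling feature set is the union of the per-tissue lists, ordered
#' lexicographically.
#'
#' @param beta Beta matrix (samples x CpGs).
#' @param samples Sample table with a `tissue` column.
#' @param k Number of sites to keep per tissue.
#' @return List of class `methformer_feature_selection` with `selected_ids`,
#'   `per_tissue_topk` (named by tissue code), and `k`.
#' @export
select_variable_cpgs <- function(beta, samples, k) {
  check_scalar(k, "k", "integer", lower = 1)
  validate_sample_table(samples, beta)
  beta <- beta[samples$sample_id, , drop = FALSE]
  tissues <- sort(unique(samples$tissue))
  cpgs <- colnames(beta)
  per_tissue <- list()
  for (t in tissues) {
    rows <- samples$tissue == t
    if (sum(rows) < 2) {
      stop(sprintf("tissue %s has fewer than 2 samples; cannot estimate variance", t),
           call. = FALSE)
    }
    v <- col_vars_imputed(beta[rows, , drop = FALSE], label = t)
    ord <- order(-v, cpgs)
    per_tissue[[as.character(t)]] <- cpgs[ord[seq_len(min(k, length(cpgs)))]]
  }
  selected <- sort(unique(unlist(per_tissue, use.names = FALSE)))
  structure(list(selected_ids = selected, per_tissue_topk = per_tissue, k = as.integer(k)),
            class = "methformer_feature_selection")
}

#' Encode covariates for modeling
#'
#' Age is z-score standardized (using supplied training statistics when given,
#' so validation/test encoding never leaks), sex passes through as a 0/1
#' indicator. Tissue codes are returned separately: they feed the tissue
#' embedding at the classifier head, not the covariate vector.
#'
#' @param samples Sample table.
#' @param age_stats Optional `c(mean, sd)` from the training set; when `NULL`,
#'   statistics are computed from `samples` and returned for reuse.
#' @return List with `covariates` (samples x 2 matrix: age_z, sex), `tissue`
#'   (integer vector), and `age_stats`.
#' @export
encode_covariates <- function(samples, age_stats = NULL) {
  validate_sample_table(samples)
  if (any(!is.finite(samples$age))) stop("ages must be finite", call. = FALSE)
  if (is.null(age_stats)) {
    m <- mean(samples$age)
    s <- stats::sd(samples$age)
    if (length(samples$age) == 1) s <- 1  # single sample: center only
    age_stats <- c(mean = m, sd = s)
  }
  if (!is.numeric(age_stats) || length(age_stats) != 2) {
    stop("age_stats must be c(mean, sd)", call. = FALSE)
  }
  if (age_stats[2] <= 0) stop("age sd must be positive", call. = FALSE)
  cov <- cbind(age_z = (samples$age - age_stats[1]) / age_stats[2],
               sex = as.numeric(samples$sex))
  rownames(cov) <- samples$sample_id
  list(covariates = cov, tissue = as.integer(samples$tissue),
       age_stats = stats::setNames(as.numeric(age_stats), c("mean", "sd")))
}

# Largest-remainder allocation of n items to fractions f (sums to n exactly;
# remainder ties resolved in the order of `f`).
largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(f))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Assigns each sample to train/val/test with per-class counts fixed by
#' largest-remainder rounding of the fractions, so class proportions in every
#' split match the global proportions to within one sample per class.
#'
#' @param samples Sample table with a `diagnosis` column.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed; the assignment is reproducible per seed.
#' @return List of class `methformer_split` with `assignment` (named character
#'   vector, values in train/val/test), `fractions`, `seed`.
#' @export
stratified_split <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  validate_sample_table(samples)
  check_scalar(seed, "seed", "integer")
  if (length(fractions) != 3 || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be 3 positive numbers summing to 1", call. = FALSE)
  }
  labels <- c("train", "val", "test")
  assignment <- character(nrow(samples))
  names(assignment) <- samples$sample_id
  with_seed(derive_seed(seed, "split"), {
    for (cls in sort(unique(samples$diagnosis))) {
      idx <- which(samples$diagnosis == cls)
      if (length(idx) < 3) {
        stop(sprintf("class %s has fewer than 3 samples; cannot split", cls), call. = FALSE)
      }
      counts <- largest_remainder(length(idx), fractions)
      idx <- sample(idx)
      assignment[idx] <- rep(labels, counts)
    }
  })
  structure(list(assignment = assignment, fractions = fractions, seed = as.integer(seed)),
            class = "methformer_split")
}

#' @export
print.methformer_split <- function(x, ...) {
  cat("stratified split:", paste(names(table(x$assignment)),
                                 table(x$assignment), sep = "=", collapse = " "),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}

#' Write / read split assignments as CSV
#' @param split A [stratified_split()] result.
#' @param path File path.
#' @export
write_split <- function(split, path) {
  utils::write.csv(data.frame(sample_id = names(split$assignment),
                              split = unname(split$assignment)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature selection as a one-column text file of CpG ids
#' @param selection A [select_variable_cpgs()] result.
#' @param path File path.
#' @export
write_feature_selection <- function(selection, path) {
  writeLines(selection$selected_ids, path)
  invisible(path)
}
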