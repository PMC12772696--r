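# Synthetic multi-tissue methylation cohorts with known ground truth.
#
# The generator emulates the statistical structure of harmonized array data:
# bimodal beta-value marginals (each CpG sits in a low- or high-methylation
# state per tissue), tissue-specific offsets, co-methylation blocks driven by
# a shared latent Gaussian factor, label-associated effect sites with a
# prescribed delta-beta, and age/sex covariates with age acting on designated
# sites. All structure is a deterministic function of the config seed, so
# holdout cohorts share the same CpG universe and causal architecture while
# drawing fresh samples.

#' Configuration for the synthetic methylation cohort generator
#'
#' @param n_samples_per_tissue Samples drawn per tissue.
#' @param n_tissues Number of tissues (contiguous integer codes from 0).
#' @param n_cpgs Number of CpG sites P (before any feature selection).
#' @param n_causal Number of label-associated CpG sites.
#' @param effect_size Delta-beta added to causal sites in cases (on the
#'   beta scale, in `[0,1]`).
#' @param block_size Width of co-methylation blocks (consecutive CpGs).
#' @param block_corr Target within-block Pearson correlation, in `[0,1)`.
#' @param age_effect Beta shift per standardized year of age at age-responsive
#'   sites.
#' @param case_fraction Fraction of cases per tissue, in (0,1).
#' @param seed Integer seed controlling all cohort structure and sampling.
#'
#' @details Background means are 0.15 (low state) and 0.85 (high state) with
#' within-state noise sd 0.08; causal sites are pinned to the low state in
#' every tissue so the planted case-minus-control difference survives
#' clipping to `[0,1]`. Ages are uniform on `[55, 95]`; sex is Bernoulli(0.5).
#'
#' @return An object of class `methformer_synth_config`.
#' @export
synth_config <- function(n_samples_per_tissue = 300L, n_tissues = 2L,
                         n_cpgs = 2000L, n_causal = 50L, effect_size = 0.25,
                         block_size = 20L, block_corr = 0.6,
                         age_effect = 0.01, case_fraction = 0.5, seed = 1L) {
  check_scalar(n_samples_per_tissue, "n_samples_per_tissue", "integer", lower = 1)
  check_scalar(n_tissues, "n_tissues", "integer", lower = 1)
  check_scalar(n_cpgs, "n_cpgs", "integer", lower = 1)
  check_scalar(n_causal, "n_causal", "integer", lower = 0)
  check_scalar(effect_size, "effect_size", "numeric", lower = 0, upper = 1)
  check_scalar(block_size, "block_size", "integer", lower = 1)
  check_scalar(block_corr, "block_corr", "numeric", lower = 0, upper = 1, upper_open = TRUE)
  check_scalar(age_effect, "age_effect", "numeric", lower = -1, upper = 1)
  check_scalar(case_fraction, "case_fraction", "numeric",
               lower = 0, upper = 1, lower_open = TRUE, upper_open = TRUE)
  check_scalar(seed, "seed", "integer")
  if (n_causal > n_cpgs) stop_field("n_causal", "must not exceed n_cpgs")
  if (block_size > n_cpgs) stop_field("block_size", "must not exceed n_cpgs")
  # low-state mean + effect must stay below 1 so the planted effect is not
  # destroyed by clipping
  if (effect_size + 0.15 > 1) stop_field("effect_size", "effect plus background mean exceeds 1")
  structure(list(
    n_samples_per_tissue = as.integer(n_samples_per_tissue),
    n_tissues = as.integer(n_tissues),
    n_cpgs = as.integer(n_cpgs),
    n_causal = as.integer(n_causal),
    effect_size = effect_size,
    block_size = as.integer(block_size),
    block_corr = block_corr,
    age_effect = age_effect,
    case_fraction = case_fraction,
    seed = as.integer(seed)
  ), class = "methformer_synth_config")
}

# Fixed generator constants (documented in synth_config)
.SYNTH <- list(
  mean_low = 0.15, mean_high = 0.85, noise_sd = 0.08,
  tissue_offset_sd = 0.03, tissue_shift_frac = 0.05, tissue_shift = 0.15,
  age_site_frac = 0.02, age_mean = 75, age_sd = (95 - 55) / sqrt(12)
)

# Cohort structure (states, offsets, causal/age sites, blocks) depends only
# on the config seed, never on the sampling seed.
synth_structure <- function(config) {
  P <- config$n_cpgs
  R <- config$n_tissues
  with_seed(derive_seed(config$seed, "structure_"), {
    block <- rep(seq_len(ceiling(P / config$block_size)), each = config$block_size)[seq_len(P)]
    state <- sample(c(0L, 1L), P, replace = TRUE)
    causal <- if (config$n_causal > 0) sort(sample.int(P, config$n_causal)) else integer(0)
    state[causal] <- 0L  # pin causal sites to the low-methylation state
    n_age <- max(0L, round(.SYNTH$age_site_frac * P))
    age_pool <- setdiff(seq_len(P), causal)
    age_sites <- if (n_age > 0 && length(age_pool) > 0)
      sort(sample(age_pool, min(n_age, length(age_pool)))) else integer(0)
    offsets <- matrix(rnorm(R * P, sd = .SYNTH$tissue_offset_sd), nrow = R)
    # a small fraction of CpGs get a pronounced tissue-specific shift
    for (t in seq_len(R)) {
      n_shift <- round(.SYNTH$tissue_shift_frac * P)
      if (n_shift > 0) {
        idx <- sample.int(P, n_shift)
        offsets[t, idx] <- offsets[t, idx] +
          sample(c(-1, 1), n_shift, replace = TRUE) * .SYNTH$tissue_shift
      }
    }
    offsets[, causal] <- 0  # keep the planted effect identical across tissues
    base_mean <- ifelse(state == 1L, .SYNTH$mean_high, .SYNTH$mean_low)
    list(block = block, state = state, base_mean = base_mean,
         causal = causal, age_sites = age_sites, offsets = offsets,
         cpg_ids = sprintf("cg%08d", seq_len(P)))
  })
}

synth_draw <- function(config, struct, sample_seed, id_prefix, cohort_name) {
  P <- config$n_cpgs
  R <- config$n_tissues
  n <- config$n_samples_per_tissue
  rho <- config$block_corr
  n_blocks <- max(struct$block)
  with_seed(sample_seed, {
    beta_list <- vector("list", R)
    tab_list <- vector("list", R)
    for (t in seq_len(R)) {
      n_case <- round(n * config$case_fraction)
      diagnosis <- sample(c(rep(1L, n_case), rep(0L, n - n_case)))
      age <- runif(n, 55, 95)
      sex <- sample(c(0L, 1L), n, replace = TRUE)
      z_block <- matrix(rnorm(n * n_blocks), nrow = n)
      eps <- matrix(rnorm(n * P), nrow = n)
      noise <- sqrt(rho) * z_block[, struct$block, drop = FALSE] + sqrt(1 - rho) * eps
      beta <- matrix(struct$base_mean, n, P, byrow = TRUE) +
        matrix(struct$offsets[t, ], n, P, byrow = TRUE) +
        .SYNTH$noise_sd * noise
      if (length(struct$causal) > 0 && config$effect_size > 0) {
        beta[diagnosis == 1L, struct$causal] <-
          beta[diagnosis == 1L, struct$causal] + config$effect_size
      }
      if (length(struct$age_sites) > 0 && config$age_effect != 0) {
        age_z <- (age - .SYNTH$age_mean) / .SYNTH$age_sd
        beta[, struct$age_sites] <- beta[, struct$age_sites] +
          config$age_effect * matrix(age_z, n, length(struct$age_sites))
      }
      beta[beta < 0] <- 0
      beta[beta > 1] <- 1
      ids <- sprintf("%s_T%d_S%04d", id_prefix, t - 1L, seq_len(n))
      rownames(beta) <- ids
      colnames(beta) <- struct$cpg_ids
      beta_list[[t]] <- beta
      tab_list[[t]] <- data.frame(
        sample_id = ids, diagnosis = diagnosis, age = age, sex = sex,
        tissue = t - 1L, cohort = cohort_name, stringsAsFactors = FALSE
      )
    }
    list(beta = do.call(rbind, beta_list), samples = do.call(rbind, tab_list))
  })
}

#' Generate a synthetic multi-tissue methylation cohort
#'
#' Draws a cohort of beta-values (samples x CpGs, in `[0,1]`) with bimodal
#' marginals, tissue-specific offsets, co-methylation blocks, planted
#' case/control effect sites, and age/sex covariates.
#'
#' @param config A [synth_config()] object.
#'
#' @return A list of class `methformer_cohort` with elements `beta` (numeric
#'   matrix, rows = samples, columns = CpGs), `samples` (data frame with
#'   columns sample_id, diagnosis, age, sex, tissue, cohort), and `truth`
#'   (list with `causal_indices`, `causal_ids`, `age_sites`,
#'   `per_tissue_offsets`, `block_assignments`).
#' @examples
#' cohort <- generate_cohort(synth_config(n_samples_per_tissue = 20, n_cpgs = 100,
#'                                        n_causal = 5, seed = 7))
#' dim(cohort$beta)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "methformer_synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  struct <- synth_structure(config)
  drawn <- synth_draw(config, struct, derive_seed(config$seed, "samples"),
                      id_prefix = "C", cohort_name = "synthetic")
  structure(list(
    beta = drawn$beta,
    samples = drawn$samples,
    truth = list(
      causal_indices = struct$causal,
      causal_ids = struct$cpg_ids[struct$causal],
      age_sites = struct$age_sites,
      per_tissue_offsets = struct$offsets,
      block_assignments = struct$block
    )
  ), class = "methformer_cohort")
}

#' Draw a holdout cohort from the same generative process
#'
#' Produces new samples from the generative process defined by `config`
#' (identical CpG universe, states, offsets, causal sites) using a disjoint
#' random stream, standing in for an independent validation cohort.
#'
#' @param config The [synth_config()] of the reference cohort.
#' @param seed Seed for the holdout sampling stream.
#' @param cpg_ids Optional CpG identifiers of the reference cohort; an error
#'   is raised if the holdout universe does not match.
#' @return A list with `beta` and `samples`; sample ids are prefixed `"H"`
#'   and never collide with the main cohort's.
#' @export
holdout_cohort <- function(config, seed, cpg_ids = NULL) {
  if (!inherits(config, "methformer_synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  check_scalar(seed, "seed", "integer")
  struct <- synth_structure(config)
  if (!is.null(cpg_ids) && !identical(cpg_ids, struct$cpg_ids)) {
    stop("holdout CpG universe does not match the reference cohort", call. = FALSE)
  }
  drawn <- synth_draw(config, struct,
                      derive_seed(seed, "holdout"),
                      id_prefix = "H", cohort_name = "holdout")
  list(beta = drawn$beta, samples = drawn$samples)
}

#' @export
print.methformer_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic methylation cohort: %d samples x %d CpGs, %d tissues, %d causal sites\n",
    nrow(x$beta), ncol(x$beta), length(unique(x$samples$tissue)),
    length(x$truth$causal_indices)
  ))
  invisible(x)
}
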