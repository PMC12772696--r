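# Shared small fixtures for the test suite.

# A tiny architecture that exercises every component (two conv stages, two
# transformer layers, multiple heads) while staying fast.
tiny_spec <- function(P = 32L, n_tissues = 2L, dropout = 0) {
  model_spec(P = P, n_tissues = n_tissues, conv_channels = c(3L, 4L),
             conv_kernel = 3L, pools = c(2L, 2L), n_layers = 2L, n_heads = 2L,
             d_cov = 3L, d_r = 2L, dropout = dropout)
}

tiny_inputs <- function(spec, B = 4L, seed = 1L) {
  set.seed(seed)
  list(
    X = matrix(runif(B * spec$P), B),
    Z = matrix(rnorm(B * spec$n_covariates), B),
    tissue = rep_len(seq_len(spec$n_tissues) - 1L, B),
    y = rep_len(c(0L, 1L), B)
  )
}

tiny_cohort <- function(seed = 7L, n = 24L, P = 60L, n_causal = 6L,
                        effect = 0.3) {
  generate_cohort(synth_config(n_samples_per_tissue = n, n_tissues = 2L,
                               n_cpgs = P, n_causal = n_causal,
                               effect_size = effect, block_size = 10L,
                               seed = seed))
}

# Fit settings that keep unit-test training fast.
fast_train <- function(epochs = 2L) {
  train_config(learning_rate = 3e-3, max_epochs = epochs, batch_size = 16L)
}

tiny_spec_args <- function() {
  list(conv_channels = c(4L, 8L), conv_kernel = 3L, pools = c(4L, 2L),
       n_layers = 1L, n_heads = 2L, d_cov = 3L, d_r = 2L)
}
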