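---
title: "methformer: model, training, and interpretability methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methformer: model, training, and interpretability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methformer)
```

This vignette documents the model and the numerical choices behind the
package. All problem sizes below are the package's own defaults, chosen so
every example runs in seconds on one CPU.

## Model

Let $x \in [0,1]^P$ be a beta-value profile over $P$ CpG sites, $z$ the
covariate vector (z-scored age, sex), and $r$ the integer tissue code.

**CpG-wise projection (margin map).** $h_p = w_p x_p + b_p$. The projection is
depthwise: site $p$ of the output depends only on site $p$ of the input, so
the signed weights $w$ read like per-site regression coefficients and are the
first interpretability view. $h$ is also the *margin map* penalized by the
margin loss below.

**Convolutional tokenizer.** Two 1-D convolution stages (kernel 9, stride 1,
zero "same" padding; GELU in the sigmoid parameterization
$x\,\sigma(1.702x)$) each followed by non-overlapping max pooling (width 4),
mapping $h$ to $L = \lceil P/16 \rceil$ tokens of width $d = 16$. Fixed
sinusoidal positional encodings over the token index are added. Internally the
convolution is computed as a sum of kernel-many shifted row-block matrix
products (in the flattened $(B\!\cdot\!P) \times C$ layout a position shift is
a row shift), which avoids materializing an im2col buffer.

**Transformer backbone.** Pre-norm residual blocks: $X \mathrel{+}=
\mathrm{Drop}(\mathrm{MHA}(\mathrm{LN}(X)))$, then $X \mathrel{+}=
\mathrm{Drop}(\mathrm{FFN}(\mathrm{LN}(X)))$, with a final layer norm.
Attention is standard scaled dot-product over $H$ heads,
$A = \mathrm{softmax}(QK^\top/\sqrt{d_h})$; the final block's per-head
matrices are retained on every forward pass for interpretability.

**Fusion and head.** The tokens are mean-pooled and concatenated with a dense
covariate embedding and a learned tissue embedding row,
$u = [\bar H; W_c z + b_c; E_{r}]$, followed by a softmax classifier.
Tissue identity enters *only* here, so attention maps are
tissue-independent by construction (asserted in the test suite).

## Training objective

For labels $y \in \{0, 1\}$ with $C$ classes, the per-sample loss is

$$\mathcal{L} = \mathrm{CE}(\tilde y, \hat p) \;+\; \alpha \cdot
\frac{1}{k}\sum_{t \in \mathrm{top}k} \max(0,\, 1 - y^{\pm} h_t),$$

where $\tilde y$ is the label-smoothed target ($1-\epsilon+\epsilon/C$ at the
true class, $\epsilon/C$ elsewhere; $\epsilon = 0.05$), $y^{\pm} = 2y - 1$,
and the hinge residuals are averaged over the $k = 64$ hardest sites (ties at
the boundary resolved by lower site index; $k$ is clamped to $P$). Predicted
probabilities are floored at $10^{-12}$ inside the logarithm.

Optimization is Adam with decoupled weight decay in two groups — the
projection weights get their own rate ($10^{-5}$) and the dense weight
matrices share another ($10^{-4}$); biases, layer norms, and the tissue
embedding are exempt. Training stops early when the validation AUC fails to
improve for `patience` epochs and the best checkpoint is returned. All
gradients are hand-derived and verified against central finite differences in
the test suite.

```{r fit}
cohort <- generate_cohort(synth_config(n_samples_per_tissue = 40, n_cpgs = 120,
                                       n_causal = 10, effect_size = 0.4,
                                       seed = 3))
fit <- methformer(cohort$beta, cohort$samples,
                  spec_args = list(conv_channels = c(4, 8), conv_kernel = 3,
                                   pools = c(4, 2), n_layers = 1, n_heads = 2),
                  train = train_config(learning_rate = 3e-3, max_epochs = 3),
                  seed = 1)
summary(fit)
```

## Synthetic cohorts

`generate_cohort()` draws multi-tissue cohorts with known ground truth:
bimodal beta marginals (low/high states 0.15/0.85, within-state noise sd
0.08), co-methylation blocks driven by a shared latent Gaussian factor
(`block_corr`), tissue-specific offsets, age acting on designated sites, and
`n_causal` label-associated sites with a prescribed $\Delta\beta$. Causal
sites are pinned to the low state so the planted effect survives clipping to
$[0,1]$, and tissue offsets are zeroed there so the effect is identical
across tissues. Structure (states, blocks, causal sites) depends only on the
config seed, so `holdout_cohort()` draws fresh samples from the identical
generative process. The generator is a stylized stand-in for harmonized array
data, not a simulator of any specific platform.

## Interpretability

**Linear weights.** `coef(fit)` returns the signed projection weights;
`rank_enrichment_test()` tests whether a site set's mean rank of $|w|$ beats
random sets (one-sided permutation test with the +1 correction).

**Grad-CAM++.** For class $c$ and a convolution stage's post-GELU map $A$
with logit gradients $G$, position weights are
$\alpha_{k,t} = G_{k,t}^2 / (2 G_{k,t}^2 + \sum_u A_{k,u} G_{k,u}^3 +
\varepsilon)$, channel weights $w_k = \sum_t \alpha_{k,t}\,
\mathrm{ReLU}(G_{k,t})$, and the map is $M_t = \mathrm{ReLU}(\sum_k w_k
A_{k,t})$, linearly upsampled to CpG resolution over the stage's
receptive-field centers ($\varepsilon = 10^{-8}$).

**Shapley.** `shapley_exact()` enumerates all coalitions (up to 14 features)
with the combinatorial weights via log-factorials; the value function
substitutes out-of-coalition coordinates with a background sample (default:
the control nearest the control centroid). `shapley_sampled()` is the
unbiased permutation estimator with per-feature standard errors;
`shap_cohort_profile()` groups contiguous CpGs into windows to keep the game
tractable. Efficiency, symmetry, and dummy axioms are asserted in the tests.

```{r shapley}
f <- function(X) X[, 1] * X[, 2] + X[, 3]
shapley_exact(f, x = c(1, 1, 1), background = c(0, 0, 0), features = 1:3)
```

**Attention.** `attention_analysis()` returns the final block's per-head
maps, their average, and per-row Shannon entropies (natural log, bounded by
$\log L$).

## Evaluation protocol

AUC uses the midrank Mann–Whitney formulation (ties contribute 1/2);
accuracy and F1 are thresholded at 0.5. `multiseed_run()` repeats
split/train/test over seeds (sd with the $n-1$ denominator); `benchmark()`
fits baseline classifiers on the identical split (train+val, since baselines
have no early stopping) and identical feature table, and compares each
baseline to the model per metric with Welch's t-test over seeds.

## Limitations

The implementation is pure R: it is practical for panels up to a few thousand
sites and cohorts of hundreds to a few thousand samples (minutes per fit on
one CPU), not for epigenome-wide matrices. The synthetic generator supports
method validation, not biological inference; effect sizes and correlation
structure are stylized. Binary diagnosis is the primary target
(`n_classes > 2` is supported by the architecture and loss, but the
evaluation helpers assume two classes).
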