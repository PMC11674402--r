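---
title: "Evaluating individual effects in predicted functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating individual effects in predicted functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbench)
```

## The question and the model

A structural-to-functional prediction model emits one matrix per subject. The
scientific claim worth testing is not "predictions correlate with empirical
functional connectivity (eFC)" — group structure guarantees that — but
"predictions are closer to *their own* subject's eFC than to other
subjects'". `fcbench` frames this as a within-subject contrast on the
cross-subject similarity matrix `r`, where `r_ij` compares prediction `i`
with empirical reference `j`:

* `r_intra(i) = r_ii`, `r_inter(i) = mean over j != i of r_ij`;
* the null hypothesis is that the mean of `d_i = r_intra(i) - r_inter(i)` is
  zero, against the one-sided alternative `d > 0` (signs are flipped for
  distance measures, where smaller is more similar).

Three inference routes are provided, in increasing robustness to the
dependence that cross-validated training induces between subjects:

1. a **naive one-sample t** (`df = N - 1`), assuming independent `d_i`;
2. a **fold-constrained permutation test**: similarity-matrix columns are
   permuted only within cross-validation folds, so between-fold dependence is
   preserved in the null ensemble; the t statistic is recomputed per
   permutation as a pivotal quantity;
3. a **corrected resampled t** for model-versus-benchmark comparisons: fold
   summaries `s_k = f(delta_model(k) - delta_benchmark(k))` are combined as
   `mean(s) / sqrt((1/K + n_test/n_train) * var(s))`, `df = K - 1`; the
   `n_test/n_train` term inflates the standard error to account for
   train/test overlap across folds. Per-fold deltas are always computed on
   the fold's own sub-similarity matrix, never across folds.

Benchmarks make the contrast meaningful: a **fold-respecting group-mean
prediction** (for each subject, the mean eFC of their training complement)
and the same mean with **elementwise Gaussian noise matched to the
training-set standard deviations**. Both carry zero subject-specific
information while matching, respectively, the group structure and the
inter-individual variance of real data.

## Statistical behaviour worth knowing

Two properties of the within-subject statistic surfaced repeatedly during
validation and are easy to misread as bugs:

**The naive t is conservative when reference heterogeneity is large.** Each
subject's eFC contributes a "typicality" effect to the whole column `j` of
the similarity matrix. These column effects cancel *exactly* in `mean(d)`
(each enters once through the diagonal and once through the inter average)
but inflate `sd(d)`. When individual covariance components are small — the
regime this package's defaults emulate — the distortion is negligible and
the test is calibrated; when they are large, the naive test under-rejects
severely. The permutation test is calibrated in both regimes, which is a
good reason to prefer it. A corollary: naive and permutation p-values agree
near the rejection tail but can differ substantially in the body of the
distribution; they should not be expected to match pointwise.

**The benchmark conditions are conservative by construction.** For subjects
outside fold `k`, their own eFC enters fold `k`'s training mean, so the
group-mean benchmark is slightly *more* similar to other folds' subjects than
to the subjects it predicts for: `d` is tilted negative and one-sided
rejection rates sit below nominal. This mirrors what the corresponding
empirical control conditions show (p-values near 1 rather than uniform) and
is the expected behaviour, not leakage: the tests remain valid (no spurious
significance), just not exact.

## Similarity measures and numerical choices

* **Pearson** similarity uses the strict upper triangle only (the diagonal is
  an uninformative constant); masked variants restrict to the prediction's
  nonzero edges, the convention for sparse structural connectomes.
* **LERM**, the log-Euclidean Riemannian metric
  `||Log(A) - Log(B)||_F`, respects the geometry of SPD correlation
  matrices. Matrix logarithms are computed by symmetric eigendecomposition.
  Because predicted matrices need not be positive definite, inputs pass
  through `spd_project()`: eigenvalues are floored at
  `floor * max(lambda_max, 1)` with `floor = 1e-6` by default. The floor is
  exposed as a parameter because no canonical treatment exists for
  near-singular inputs; at the default it perturbs full-rank sample
  correlation matrices by amounts far below sampling noise. LERM is only
  offered on raw (unstandardized) matrices — z-scored matrices are not
  correlation matrices and have no SPD interpretation. The affine-invariant
  Riemannian metric is deliberately not implemented (its matrix inversions
  are impractical at connectome dimensionalities).
* **Assignment**: subject matching solves the linear sum assignment problem
  (Hungarian method, via `clue::solve_LSAP`) on the similarity matrix
  (negated for correlations; distances minimized directly). Entries are
  shifted by a constant to meet the solver's nonnegativity requirement,
  which cannot change the optimal permutation. Matching accuracy is
  invariant to positive affine transforms of the similarities but *not* to
  general monotone transforms, which re-weight sums. Ties are resolved by
  the solver's deterministic behaviour on a fixed subject order.
* **Degenerate inputs** are handled explicitly: zero-variance off-diagonal
  vectors raise classed errors; zero-variance difference vectors yield
  `t = 0, p = 0.5` (all-zero) or `p in {0, 1}` with a degeneracy flag;
  z-scored elements with training standard deviation below `1e-12` are set
  to 0; evaluation-grid conditions that are undefined (e.g. the z-scored
  group-mean benchmark at K = 2, where all training predictions coincide)
  are recorded as skipped rather than failing the run.
* **Permutation p** uses the add-one estimator `(1 + count)/(1 + n_perm)` —
  never exactly zero — alongside a normal-approximation binomial 95%
  interval. Bootstrap fold comparisons use one-sided 95% percentile lower
  bounds (not BCa); a fold is significant when its bound exceeds zero.
* The fold summary `f` defaults to the **median** (per-subject deltas are
  skewed); the mean is available. Matrices asymmetric by at most `1e-8`
  (relative) are silently symmetrized as `(M + t(M))/2`; anything worse is an
  error. All headline tests are one-tailed; two-tailed variants exist for
  exploration.

## The synthetic cohort generator

`generate_cohort()` realizes each subject's eFC as the sample correlation
matrix of `t_samples` latent draws from
`(1 - alpha) * Sigma_G + alpha * Sigma_i`, with the group covariance
`Sigma_G` and individual covariances `Sigma_i` drawn as low-rank factor
models `A A' + I` (rank `n_nodes/4`, giving realistic eigenvalue decay).
Predictions use an *independent* set of draws whose individual component is
`beta * Sigma_i + (1 - beta) * nuisance`: `beta` is prediction fidelity, with
`beta = 0` the exchangeable null. Because matrices are realized through
latent samples, symmetry, unit diagonal and positive semidefiniteness are
structural — nothing is patched after the fact — and `t_samples > n_nodes`
guarantees full rank, so LERM needs no meaningful flooring. Structural
connectomes couple to the same `Sigma_i`: off-diagonal couplings plus noise
are thresholded to the top `sc_density` fraction, and surviving edges are
rank-mapped onto Normal(5, 1) quantiles floored at a tiny positive value — a
log-streamline-count flavour that keeps SC nonnegative by construction.

Defaults state the emulated world: `n_nodes = 68` (a standard cortical
parcellation), `t_samples = 300` (resting-state scan length at typical
sampling), `K = 10` folds, and `alpha = 0.1` — group structure dominates and
individual effects are small but stable, which is the regime reported for
real cohorts (observed effect sizes around `d = 0.06`) and the regime in
which the naive test is calibrated (see above). `sc_density = 0.5` reflects
deterministic-tractography connectomes at this parcellation.

What the generator does **not** emulate: spatial/anatomical structure (no
geometry, no hemispheres), heavy-tailed motion artifacts, site effects, and
— importantly — *cross-validation-induced dependence between folds*, since
no model is actually trained. A green calibration test therefore establishes
that the statistics behave correctly under exchangeable nulls with realistic
covariance structure; it does not certify behaviour under adversarial
training leakage, which is exactly what the fold-constrained permutation and
corrected-t machinery is there to absorb on real data.

## Open design decisions

* **Whose moments for z-scoring?** The empirical account says eFC and
  predictions were standardized but not with whose training moments. Each
  stack is z-scored with its *own* training-fold moments (eFC with eFC
  moments, predictions with prediction moments); this is switchable by
  passing a different `moments_source` to `fold_zscore()`.
* **Noise clipping:** benchmark noise is not clipped to `[-1, 1]`; clipping
  would shrink the matched variance, breaking the property the benchmark
  exists for.
* **Percent improvement** is `(r_model - r_reference)/r_model * 100` with
  the reference taken as the noisy-benchmark intra-similarity. Note that the
  published headline value computed from this formula's printed inputs
  (0.547, 0.477) evaluates to about 12.8%, not the printed 9.1%; the formula
  is implemented exactly as defined and the discrepancy is documented here
  rather than resolved.
* **Differential identifiability** (mean diagonal minus mean off-diagonal)
  is provided as a descriptive convenience only, without a significance
  test: its two-sample framing assumes independence that cross-validated
  predictions violate.
* **Chance matching** uses column permutation of the similarity matrix (the
  Gaussian-matrix alternative is reported to behave equivalently and is not
  implemented). Subset folds are chosen uniformly among folds large enough;
  with equal fold sizes this coincides with size-proportional choice.
* **Manifest format** is an artifact convention (tab-separated manifest plus
  headerless delimited square matrices, comma/tab auto-detected): external
  pipelines must supply fold labels, because benchmarks and permutation must
  respect the folds used in training; the simulator assigns its own.

## Known limitations

* The naive test's conservativeness at large individual-component shares is
  inherent to the statistic, not fixable by tuning; use the permutation test
  when reference heterogeneity is substantial.
* Bootstrap lower bounds are percentile-based and can be anti-conservative
  for very small folds (n < ~8); fold sizes below 3 are refused.
* LERM runtimes are dominated by per-matrix eigendecompositions (O(N p^3)
  for the similarity matrix); Pearson similarity is vectorized and fast.
* The simulator's SC is a statistical stand-in (coupled sparsity + rank
  transform), not a biophysical forward model; SC-based conclusions should
  be read as tests of the *pipeline*, not of tractography realism.
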