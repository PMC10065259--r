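---
title: "Integrating longitudinal multi-omic mouse studies with latent factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating longitudinal multi-omic mouse studies with latent factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dystrophic mouse models (mdx and the utrophin-modulated mdxUtrnPP and
mdxUtrnPM lines) are followed for months with repeated blood sampling, but
the affected tissue — skeletal muscle — can only be assayed at sacrifice.
A typical design produces four omic views with very different shapes:
muscle RNA-seq (one sample per mouse, at the final week), blood RNA-seq,
plasma lipids and plasma metabolites (repeated over weeks, but a single
blood draw cannot feed both the RNA and the LC-MS tracks, so the latter
three views observe partially disjoint samples). The scientific questions
are whether coordinated molecular programs span these views, how they
relate to genotype and to age, and whether blood readouts can proxy for
muscle pathology.

`momfa` implements that entire analysis as a tested pipeline: a synthetic
study generator with known ground truth, per-view normalization, matching
of samples into multiomic profiles, a multi-view latent factor model
fitted by variational Bayes, an ensemble training/selection protocol, and
factor-phenotype association tests.

## The model

Each preprocessed view $m$ is a profiles-by-features matrix $Y_m$
decomposed as

$$ Y_m = Z W_m^\top + E_m $$

with a single matrix of factor scores $Z$ (profiles $\times$ K) shared by
all views, view-specific loadings $W_m$, and Gaussian residuals $E_m$
with per-feature precision $\tau_{md}$. Priors are standard normal on the
entries of $Z$, normal with per-(view, factor) ARD precision
$\alpha_{mk}$ on loadings, and vague Gamma(1e-3, 1e-3) on all precisions.
Inference is coordinate-ascent mean-field variational Bayes with conjugate
updates for $q(W)$, $q(Z)$, $q(\alpha)$ and $q(\tau)$, cycled until the
relative change of the evidence lower bound (ELBO) stays below `tol`
(default 1e-6) on two consecutive iterations. The likelihood and all
sufficient statistics run over *observed* profiles only, so the pervasive
missingness of the design needs no imputation; `reconstruct()` afterwards
provides model-based predictions for the unobserved cells.

Two implementation details matter for correctness and speed:

* The covariance of $q(w_{md})$ is $(\mathrm{diag}(\alpha_m) + \tau_{md}
  S_m)^{-1}$ with $S_m = \sum_{n} \mathbb{E}[z_n z_n^\top]$ shared by all
  features of a view. One eigendecomposition of the
  $\alpha$-whitened $S_m$ per view per iteration therefore yields every
  feature's covariance in closed form — no per-feature matrix inversions.
* Profiles sharing the same pattern of observed views share their score
  covariance, so $q(Z)$ updates group by pattern (a handful of patterns in
  this design) rather than by profile.

### Factor pruning and the ELBO trace

Fitting starts from `k_init` factors (SVD of the zero-filled concatenated
views, perturbed with seed-dependent noise). Every 5th iteration after a
10-iteration burn-in, a factor whose variance-explained fraction is below
`threshold` in **every** view is dropped; clearing the threshold in any
single view saves it, so view-specific factors survive. Pruning changes
the model dimension, and a bound across different dimensions is not
comparable, so `elbo_trace` reports the iterations since the last pruning
event — within which the bound is non-decreasing (slack 1e-6, asserted in
the tests) — while `elbo_segments` keeps the full segmented history.

Factors are returned ordered by total variance explained, with signs fixed
so each factor's largest-magnitude loading is positive. Variance explained
follows the usual convention: per-factor
$R^2(m,k) = 1 - \sum(Y_m - z_k w_{mk}^\top)^2 / \sum Y_m^2$ clipped at 0,
per-view totals from the full reconstruction (not the per-factor sum,
which would double-count under correlated factors), and the overall total
as the observed-entry-count weighted mean of per-view totals.

## The training and selection protocol

Because the variational objective is non-convex and the converged number
of factors depends on the threshold and the seed, a single fit is not
trustworthy. `run_ensemble()` therefore fits a full grid — by default 8
pruning thresholds evenly spaced on [0.02, 0.20] times 100 seeds, i.e.
800 fits — with the collision-free seed schedule
`base_seed + i * 10^4 + j`. `select_best_per_k()` groups fits by their
converged factor count and keeps the highest-ELBO fit per group (ELBO
ranking is only meaningful within equal K on the same data; the absolute
values are implementation-specific). `selection_curve()` then tabulates
total and per-view variance explained against K, and `select_model()`
chooses the smallest K whose gain to the next candidate falls below
`elbow_delta` (default 0.01 absolute). The elbow choice in practice is
often made by eye; the automated rule makes the workflow reproducible and
`k_override` reproduces any visual choice exactly.

## Preprocessing choices

* **RNA views**: genes are kept when they reach 5 cpm (computed on raw
  library sizes) in at least 10% of samples, both bounds inclusive.
  Between-sample scale factors use the trimmed mean of M-values with the
  standard published trims (30% of M-values and 5% of A-values from each
  tail, precision-weighted); the implementation is cross-checked against
  edgeR to 1e-10 in the tests. Counts become `log2(cpm + 1)`; the log is
  configurable off, but variance ranking on raw cpm is dominated by a few
  high-abundance genes, so the log is the default. Each RNA view is then
  capped to its `top_k_genes` (default 2500) highest-variance genes so
  that the much smaller lipid and metabolite views are not swamped in the
  factor fit.
* **LC-MS views**: probabilistic quotient normalization with the median
  spectrum as reference (configurable to mean) divides out per-sample
  dilution; the generator injects known log-normal dilutions and the tests
  require recovery within 5%.
* **Scaling**: all views are centered per feature and scaled to unit
  variance before fitting. Centering is required by a factor model without
  intercepts; scaling removes the gross scale differences between
  sequencing counts and spectrometry intensities.

Matching assembles profiles by the (mouse, group, week) key; where a view
holds several samples for one key, normalized values are averaged per
feature (refused for raw counts, where averaging would mix library
sizes). The uniform averaging rule applies to every view, and a mouse
with both blood-RNA and plasma assays in one week keeps both in a single
profile.

## What the generator emulates — and what it does not

`simulate_study()` reproduces the study conditions: 40 mice in 4 groups
(10 per group; the per-group split is symmetric by assumption), weeks
6–30 in steps of 6, muscle only at week 30, and a Bernoulli(0.5)
assignment of each (mouse, week) pair to the blood-RNA or plasma track.
Three true factors drive the views through sparse loadings (50% zeros):

* a **disease** factor — dystrophic groups offset by 2 score units from
  WT plus a week-6 offset of 2, residual SD 0.6;
* a **growth** factor — slope 1/6 per week in all groups, residual SD 1.5;
* an **early-disease** factor — week-6 offset of 2 in dystrophic groups
  only, residual SD 0.8.

The residual SDs are calibrated so that group and week jointly explain
roughly 80%, 45% and 45% of the three factors' variance — the magnitudes
reported for the leading disease, growth and early factors in longitudinal
dystrophic-mouse studies. Each factor is active in a different subset of
views (disease everywhere; growth everywhere except muscle; early disease
in the two RNA views). This differential activity mirrors how real
multi-omic factors are partly view-specific, and it is also what makes
factors identifiable up to sign: with every factor equally active in every
view, the Gaussian model is rotation-invariant and no method can recover
individual factors.

RNA counts are negative-binomial (dispersion 0.05) around per-sample
proportions `softmax(baseline + W Z')`, so library size and composition
stay decoupled and TMM has real work to do; plasma abundances are
log-normal with per-sample dilution multipliers (log-SD 0.4), so PQN has
real work to do. The generator makes no attempt at realistic gene
identities, pathway structure, count zero-inflation, or batch effects —
passing tests demonstrate that the pipeline's statistics behave as
designed under the stated generative assumptions, not that any particular
biological conclusion transfers to real data.

## Association tests

For each factor, `lf_anova()` fits `score ~ group`, `score ~ week` and
`score ~ group * week` by least squares with both covariates categorical,
reporting each $R^2$ and the overall F-test p-values of the two
main-effect models, BH-adjusted across factors separately within the
group family and the week family (matching the two adjusted columns such
association tables carry). Conventions for degenerate cases are explicit:
a constant factor reports $R^2 = 0$, $p = 1$; p-values are floored at
1e-300 so perfect separation cannot overflow to zero; a group or week
level with fewer than two profiles flags the row. Pairwise contrasts use
two-sided t-tests with the pooled one-way variance (classical post-hoc
contrasts; Welch available by flag since the underlying test is a
convention, not a law), BH-adjusted within each (factor, family).
`threshold_loadings()` uses a strict `|loading| > cutoff` with the cutoff
interpreted on loadings fitted to unit-variance data, and
`cross_view_loading_comparison()` inner-joins loadings of the two RNA
views by gene ID to ask whether the same genes drive a factor in muscle
and blood.

## Numerical and design notes

* All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce every artifact bit-for-bit (asserted).
* `k_init` above `min(n profiles, total features)` is clamped with a
  warning; a view with no observed profile is an error.
* The ELBO is re-evaluated exactly by `elbo(fit, ps)` from the fit's
  stored variational state; a quadrature oracle in the test suite checks
  the bound's expectation algebra term by term on a tiny instance.
* On very small instances (a handful of profiles) the Bayesian Occam
  penalty can legitimately prefer the factorless model and prune
  everything; `k_active = 0` is a valid result, and `reconstruct()` then
  returns zeros.
* Interchange formats are TSV plus a JSON manifest per fit — portable and
  diffable; no binary containers.

## Problem sizes used in the shipped runs

The demonstration workflow under `analysis/` and the verification script
`scripts/acceptance.R` run the full statistical protocol at moderate
sizes chosen as the package's own defaults for a desk-scale study:
hundreds of genes per RNA view (cap 200 in the workflow config) rather
than tens of thousands, the full 8 x 100 ensemble grid on a 20-profile
four-view set, factor-recovery checks over 20 replicate 100-profile
studies, and a reduced 2-threshold x 3-seed ensemble inside the
end-to-end run. The protocol — not the scale — is the object under test;
all sizes are configurable upward through `run_config()` and
`truth_model()`.

## Known limitations

* Gaussian likelihoods only; count views enter after cpm-log
  transformation rather than through a count likelihood.
* ARD shrinkage biases small loadings toward zero, and score posteriors
  for profiles observed in few views are shrunk toward the prior mean —
  visible as a few-percent attenuation of imputed values in the tests.
* No spike-and-slab sparsity, no batch correction, no pathway enrichment;
  factor interpretation beyond loadings and phenotype association is out
  of scope.
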