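# momfa — longitudinal multi-omic factor analysis for dystrophic mouse studies

`momfa` is an R package plus analysis workflow for integrating the four
omic views of a longitudinal dystrophic-mouse experiment — muscle RNA-seq,
blood RNA-seq, plasma lipidomics and plasma metabolomics — into a small
set of shared latent factors, and for relating those factors to genotype
group (WT, mdx, mdxUtrnPP, mdxUtrnPM) and age (weeks 6–30).

The core is the multi-view decomposition

```
Y_m = Z W_m' + E_m ,   m = muscle RNA, blood RNA, lipids, metabolites
```

with shared factor scores `Z` (one row per multiomic profile), view-specific
loadings `W_m`, and Gaussian noise `E_m` with per-feature precision.
It is fitted by mean-field variational Bayes with automatic relevance
determination on the loadings, variance-threshold factor pruning, and the
likelihood evaluated over observed profiles only — the design's heavy
missingness (muscle only at sacrifice; each blood draw feeding either the
RNA or the LC-MS track) needs no imputation. Because the objective is
non-convex, training follows an ensemble protocol: a grid of pruning
thresholds × random seeds, the best fit per factor count by ELBO, and an
elbow rule on total variance explained to choose the final model.

Around the core, the package provides:

* a synthetic-study generator with known ground truth (`simulate_study()`),
  emulating 40 mice in 4 groups, 6-weekly blood draws, muscle at week 30,
  negative-binomial RNA counts and dilution-confounded LC-MS abundances;
* the preprocessing rules of the protocol: a ≥5-cpm-in-≥10%-of-samples
  expression filter, TMM scale factors (cross-checked against edgeR),
  log2 normalized cpm, probabilistic quotient normalization, per-view
  top-variance gene caps, and unit-variance scaling;
* profile matching by (mouse, group, week) with duplicate averaging and
  missingness accounting (`match_profiles()`);
* factor–phenotype association: per-factor R² and F tests for group,
  week and their interaction, Benjamini–Hochberg adjustment, pairwise
  contrasts, top-loading and cross-view loading summaries.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
its six scripts in order reproduces a complete study analysis from
nothing. Step 1 simulates the study, steps 2–3 preprocess and match:

```
$ Rscript analysis/01_simulate.R
simulated 344 samples over 40 mice; per-view sample counts:
 muscle_rna   blood_rna      lipids metabolites
         40          96         104         104

$ Rscript analysis/03_match.R
profile_set: 200 profiles, 4 views
  muscle_rna     200 features,  40/200 profiles observed
  blood_rna      200 features,  96/200 profiles observed
  lipids         120 features, 104/200 profiles observed
  metabolites     60 features, 104/200 profiles observed
```

Every (mouse, week) pair becomes one multiomic profile; 344 omic samples
land in 200 profiles, each observed in at least one view. Steps 4–5 fit
the ensemble (8 thresholds × 5 seeds in the shipped config) and select
the factor count where total variance explained levels off:

```
$ Rscript analysis/05_select.R
selected K = 5 | gain from K=5 to K=6 is 0.0034 < elbow_delta = 0.0100
variance explained (fractions):
               LF1    LF2    LF3    LF4    LF5  total
muscle_rna  0.0003 0.4308 0.0005 0.0002 0.3578 0.9266
blood_rna   0.5241 0.0599 0.0693 0.2376 0.0675 0.9290
lipids      0.0485 0.2300 0.3186 0.0391 0.0204 0.6583
metabolites 0.0544 0.2654 0.3679 0.0389 0.0116 0.7365
overall total: 0.8288
```

The chosen 5-factor model explains 82.9% of the variance in the matched
dataset, more in the RNA views than in the smaller LC-MS views. Step 6
relates factors to phenotype:

```
$ Rscript analysis/06_associate.R
  factor r2_group r2_week r2_interaction  p_group   p_week  q_group   q_week
1    LF1  0.09886   0.204          0.349 1.37e-04 4.78e-09 3.42e-04 2.39e-08
2    LF2  0.39886   0.140          0.570 1.56e-21 6.07e-06 7.80e-21 1.01e-05
...
4    LF4  0.00145   0.177          0.313 9.63e-01 1.01e-07 9.63e-01 2.52e-07
```

LF2 is the disease factor the generator injected: strongly associated
with both genotype group (R² = 0.40, q ≈ 8e-21) and week, and active in
all four views. LF4 shows the pure-time signature of the injected growth
factor (q_week ≈ 2.5e-7, q_group ≈ 0.96). Pairwise group/week contrasts,
top-10 loadings per view, and the muscle-vs-blood loading comparison are
written under `results/`.

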