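---
title: "Statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

lfqpipe analyses label-free quantification (LFQ) proteomics intensity
data — typically a MaxQuant `proteinGroups.txt` table — from raw parsing
through differential abundance to cross-validated biomarker panels. This
vignette records the statistical model, the defaults and why they were
chosen, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

# The data model

A protein-level LFQ table holds, per protein group, linear-scale
intensities across samples plus quality annotations: decoy
("reverse") rows from target-decoy searching, known contaminants, rows
identified only by modification site, and unique-peptide counts. All
analysis happens on the log2 scale. A zero intensity in MaxQuant output
does not mean "measured as zero" — it means the protein was not
quantified in that run, usually because its abundance fell below the
detection limit. lfqpipe therefore converts zeros to missing values
before the log transform, and treats missingness as left-censored
(missing-not-at-random, MNAR) throughout.

## Filtering defaults

* Contaminant / reverse / only-by-site rows are always removed.
* Proteins identified by two or fewer unique peptides are removed
  (`uniq_pep_min = 3`); identifications supported by one or two
  peptides are too unreliable for quantitative comparison. The cutoff
  is a parameter; for generic intensity matrices (no peptide counts)
  this filter is skipped with a notice.
* Group-wise missingness: a protein is kept only if, in *every* group,
  its missing fraction is at most `max_group_na` (default 0.34, i.e.
  more than 34% missing in any one group removes it). The comparison is
  strict ("greater than removes"), with a 1e-12 slack on the threshold
  so exact rational boundaries (one missing of three at a 1/3
  threshold) land on the "keep" side rather than depending on binary
  rounding.

Technical replicates, when declared in the design, are averaged
arithmetically on the log2 scale over observed values only; a sample's
value is missing only when every one of its technical replicates is.
Averaging after the log transform matches the pipeline order (the log2
table is the unit all downstream stages consume).

# MinProb imputation

Missing values are replaced by draws from a Gaussian centred near the
bottom of each sample's observed distribution:

* centre: `mu_j` = the `q`-th quantile (default `q = 0.01`, type-7
  linear interpolation) of column *j*'s observed values — a proxy for
  the sample's detection limit;
* spread: `sigma = tune_sigma * median_g sd_g`, the tuned median of the
  per-protein standard deviations of observed values (default
  `tune_sigma = 1`).

With `tune_sigma = 0` every imputed value in column *j* is exactly
`mu_j`, which makes the imputation deterministic and bit-reproducible —
useful as a degenerate test case. One seeded generator serves the whole
call and draws are consumed column by column, so results do not depend
on any parallel execution plan. The per-column centres, the common
spread and the seed are recorded in a sidecar JSON by the workflow
runner. `q` and `tune_sigma` are conventions of this left-censored
imputation family, surfaced as parameters; they are package defaults,
not empirical estimates.

# Quantile normalization

Samples are forced onto one common intensity distribution: the value at
rank *r* in each column becomes the mean across columns of the rank-*r*
order statistics; ties receive the mean of their tied targets. Columns
containing missing values are normalized by linear interpolation of the
mean quantile function at the observed entries' quantile positions,
leaving missing entries missing. The computation is delegated to
`limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
rule; within-column rank order of observed values is preserved by
construction. Normalization and imputation compose in either order
(`impute_first`, `normalize_first`), and `skip_normalization` is
supported for data already normalized upstream (e.g. MaxLFQ output).

# Differential abundance

Per protein *g*, with groups A and B (A = first group in the design
file; the contrast direction is recorded in the result header):

* `beta_g = mean_A - mean_B` (log2 fold change),
* pooled residual variance `s2_g` on `d = n_A + n_B - 2` degrees of
  freedom, and `v = 1/n_A + 1/n_B`.

With a handful of replicates, per-protein variances are noisy;
empirical-Bayes variance squeezing shares information across proteins
through a scaled inverse-chi-square prior with parameters `(d0, s02)`.
These are estimated by moment matching on
`e_g = log s2_g - digamma(d/2) + log(d/2)`: with `ebar` the mean and `V`
the unbiased variance of the finite `e_g`, set
`V' = V - trigamma(d/2)`; if `V' > 0`,

    d0  = 2 * trigammainv(V')
    s02 = exp(ebar + digamma(d0/2) - log(d0/2))

otherwise the observed variances are *less* dispersed than chi-square
sampling noise alone predicts, and the prior is degenerate:
`d0 = Inf`, `s02 = exp(ebar)`. The trigamma inverse is solved by damped
Newton iteration to `|delta| < 1e-8` (the damping halves any step that
would cross zero; trigamma is positive, decreasing and convex, so the
iteration converges). Proteins with `s2 = 0` (possible after constant
imputation) are excluded from the moment estimation — their log
variance is undefined — but still receive the posterior
`d0*s02/(d0+d)`.

The posterior variance `s2~ = (d0*s02 + d*s2_g)/(d0 + d)` always lies
between `s2_g` and `s02`, and the moderated statistic

    t_g = beta_g / sqrt(s2~ * v)

is referred to Student-t on `d + d0` degrees of freedom (the normal
tail when `d0 = Inf`; the ordinary pooled two-sample t when `d0 = 0`).
Zero posterior variance yields `t = +/-Inf`, `p = 0`, flagged in the
output. Multiple testing uses the Benjamini–Hochberg step-up
(implemented directly; `stats::p.adjust` is an independent cross-check
in the tests, and other `p.adjust` methods can be requested). A protein
is *significant* when `|log2FC| > 1` **and** adjusted p `< 0.05`, both
strict inequalities; results are sorted by adjusted p, ties broken by
larger `|log2FC|`, then protein ID.

The implementation is verified against `limma::squeezeVar`/`eBayes` on
shared inputs, against the pooled t at `d0 = 0`, and by parameter
recovery from 5,000 variances simulated from the scaled-F sampling
model (`d0 = 4`, `s02 = 1`, `d = 4`; recovered within 15% and 5%
respectively).

# Biomarker modeling

* **Feature selection.** The up-to-20 significant proteins with the
  smallest adjusted p enter correlation pruning: while any feature pair
  has `|r| > 0.90` (Pearson across samples), the member of the worst
  pair with the larger mean absolute correlation to the remaining
  features is removed (ties: the one later in the significance order).
  Zero-variance features are dropped first, with a warning. Selection
  re-derives the significance ordering internally, so it is invariant
  to the row order of its input.
* **Split.** Stratified: each class with `n_c` samples contributes
  `round(0.7 * n_c)` training samples (round half up, floored at one
  sample per class per partition), drawn without replacement under the
  seed. A single documented rounding rule was fixed because per-class
  arithmetic admits several conventions.
* **Training.** `caret::train` with stratified k-fold cross-validation
  (default `k = 10`, `repeats = 3`, i.e. 30 resampling measurements per
  candidate hyperparameter setting) over small fixed grids, selecting
  the setting with the highest mean accuracy (Cohen's kappa is
  reported, not used for selection). The registry maps the workflow's
  algorithm names onto native backends: `rf` (randomForest),
  `svmRadial`/`svmLinear` (kernlab), `glm` (binomial GLM), `knn`
  (class), `naive_bayes` (a custom caret model spec over
  `e1071::naiveBayes` — Gaussian naive Bayes), and `xgbLinear` (a
  custom caret model spec over xgboost's `gblinear` booster,
  single-threaded for reproducibility: gradient boosting with linear
  base learners, a close native equivalent of the usual
  "boosted linear" method). Grids are pinned in code and recorded in
  the run report, because reproducibility requires known grids.
* **Evaluation.** Held-out class probabilities per algorithm
  (row-normalized within 1e-9; argmax prediction, ties resolved toward
  the first class in design order), confusion matrices, and ROC/AUC.
  The ROC is computed at every distinct score threshold with endpoints
  (0,0) and (1,1); the AUC is the Mann–Whitney pair-counting statistic
  (ties count 1/2), which equals the trapezoidal integral of that ROC —
  both are computed in the tests and compared to 1e-12, plus a
  cross-check against pROC. The positive class defaults to the second
  class in design order and is recorded in the report.
* Variable importance is *permutation importance* on the training
  partition (mean accuracy drop over 5 permutations of one feature's
  values), one portable, model-agnostic definition applied to every
  algorithm.

Gaussian naive Bayes needs at least two training samples per class in
every fold to estimate a variance; with very small experiments (e.g.
three biological replicates per group) choose `k = 2` and algorithms
that tolerate one-sample folds (`glm`, `rf`), as the end-to-end example
below does.

# The synthetic-data generator

`simulate_lfq_experiment()` produces a MaxQuant-dialect table with full
ground truth, emulating:

* log-normal protein abundances (`base_mean = 25`, `base_sd = 2` on the
  log2 scale, typical of LFQ magnitudes);
* group effects of `+/- effect_log2` (default 2) on `n_de` proteins in
  the second group;
* biological replicate noise `sigma_within` (default 0.5 log2 units),
  with technical replicates scattering around their biological value at
  half the variance (`sigma_within/sqrt(2)`) — technical replicates
  should be tighter than biological ones, so replicate-averaging and
  replicate-correlation plots have signal;
* left-censored dropout: a cell at log2 intensity `x` is zeroed with
  probability `plogis(mnar_steepness * (c - x))`, `c` the
  `mnar_center` quantile (default 0.1) of all simulated intensities.
  `mnar_steepness = 0` disables dropout entirely (a literal zero-slope
  logistic would drop half of all cells uniformly — useless as a
  control condition);
* decoy rows (contaminant / reverse / only-by-site, 2% each by default)
  drawn from the same abundance distribution with 1–10 unique peptides;
  genuine proteins get 3–30, so they pass the default peptide filter
  and the decoys exercise it.

What the generator does **not** emulate: peptide-level identification
and roll-up, shared/razor peptides, retention-time effects,
batch/run-order drift, and intensity-dependent variance
(heteroscedasticity beyond censoring). Tests passing on this generator
therefore demonstrate the correctness of the implemented procedures
under their stated assumptions, not performance on any particular real
dataset.

# Verification scales and outcomes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch) uses these problem sizes, chosen to make
each statistical check sharp while keeping the whole suite quick to
run:

* BH step-up vs brute force: 1,000 random vectors, length ≤ 12.
* Shrinkage bounds: 10,000 random variances; prior recovery: 5,000
  simulated scaled-F variances.
* Null calibration: 2,000 proteins, 3 vs 3, Gaussian; expects uniform
  p-values (KS at alpha = 0.01) and ≤ 1% flagged.
* Power/FDR: 20 generator runs of 500 proteins with 50 true effects at
  `|log2FC| = 2`, `sigma_within = 0.5`, 3 per group, dropout disabled
  (the check isolates the test's operating characteristics from
  imputation); expects mean recall ≥ 0.8 at mean observed FDR ≤ 0.10.
* Imputation: 10,000 imputed values in one column, KS against the
  implied Gaussian; exact quantile reproduction at `tune_sigma = 0`.
* Modeling: a linearly separable two-class frame (16 per class, 5
  features, centroid gap 16 noise SDs) on which every registry
  algorithm must reach ≥ 0.95 CV accuracy and perfect held-out
  classification; and chance-level calibration on permuted labels
  (40 samples, 20 noise features), where the mean CV accuracy is
  averaged over 5 independent permutations because a single label draw
  on 40 samples leaves the estimator with sizeable variance (the folds
  all reuse one dataset).
* End-to-end: simulate → analyze → model on a 500-protein, 2×3
  biological × 3 technical replicate fixture, checking the full
  artifact set and byte-identical reruns under fixed seeds.

# Known limitations

* Exactly two groups per contrast; multi-factor designs, blocking and
  paired tests are out of scope.
* One imputation family (MinProb) and one normalization (quantile);
  deliberate, to keep the pipeline auditable.
* The design-file schema (`sample`, `group`, optional `tech_rep`) is
  this package's convention; other tools use different layouts.
* Class-imbalance handling is not provided; subset to balanced classes
  before modeling.
* Dropout in the generator depends on intensity only through one
  logistic; real MNAR patterns also vary by run and peptide.
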