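---
title: "Dissecting and predicting stimulated cytokine responses: models and methods"
author: "cytopredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting and predicting stimulated cytokine responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-blood stimulation assays measure how much cytokine (pg/ml) an
individual's immune cells secrete after a defined trigger — an innate
stimulus such as a Toll-like-receptor (TLR) agonist, or an adaptive one such
as T-cell-receptor (TCR) engagement. These responses vary enormously between
healthy people, and the variation has heterogeneous sources: common genetic
variants, blood cell composition, age, sex, BMI, CMV serostatus, hormones,
and the season in which the sample was drawn. `cytopredict` implements a
complete machine-learning pipeline for dissecting that variation and
predicting individual responses from genotype dosages plus biological and
environmental covariates, with the feature-selection step explicitly
leakage-controlled, and with a synthetic-cohort generator so that every
stage can be exercised and validated without access to individual-level
human data.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate cohorts whose statistical
structure matches the assumptions of every downstream stage.

**Genotypes.** Variants come in independent LD blocks. Each block carries a
pool of `haplotype_pool_size` (default 8) haplotypes; a variant's allele
frequency is drawn uniformly from `maf_range` (default [0.05, 0.5], i.e. a
post-QC panel) and realized exactly in the pool, so every variant is
polymorphic and its population frequency is known analytically. Each
individual receives the sum of two haplotypes drawn independently from the
pool, giving Hardy–Weinberg genotypes with strong within-block LD (a pool of
2 gives r² = 1 within a block) and exact cross-block independence. Blocks
span < 250 kb with > 1 Mb gaps, so the C+T clumping window never bridges
blocks. The default panel is 50 blocks × 40 variants = 2,000 variants;
replicated experiments below state their own sizes.

**Covariates.** Age (uniform 20–60), sex (Bernoulli 0.5), BMI (truncated
normal, mean 23.5, sd 2.5, bounds 17–32), collection day-of-year (uniform
1–365), five blood cell counts and three sex hormones (log-normal, hormone
location shifted by sex), CMV serostatus (Bernoulli 0.35).

**Cytokine traits.** On the log2 scale,

y = intercept + Σ βⱼ gⱼ + γ_age·age* + γ_cmv·CMV + a·s1 + b·s2 +
γ_mono·mono* + γ_sex·sex + ε,

where s1 = sin(2π·doy/365), s2 = cos(2π·doy/365) place each sample on the
unit circle of the year, starred covariates are standardized by their
theoretical moments (so the same coefficients transfer exactly to any
cohort drawn from the configuration), and ε ~ N(0, noise_sd²). Causal
variants occupy distinct blocks; their effects are scaled analytically from
the known pool frequencies so the planted genetic variance equals
`h2_genetic` in expectation. Three archetypes encode the empirically
observed dichotomy between stimulation classes:

* `TCR_LIKE` — genetics-dominant: 5 causal variants, h² = 0.25, modest
  age/CMV/sex effects, no seasonality or monocyte effect.
* `TLR_LIKE` — environment-dominant: 20 tiny causal variants (h² = 0.05),
  strong seasonal amplitudes (a = 0.4, b = 0.25) and monocyte effect (0.4).
* `NULL` — pure noise; the negative control for calibration and the
  leakage experiment.

Coefficients were chosen once so that total trait variance is ≈ 1 and the
variance partitions are plausible for immune traits; `noise_sd` defaults to
the remainder. The generator records a `truth` object (causal IDs, betas,
environmental coefficients, theoretical variance fractions) for
parameter-recovery tests.

**What the generator does not emulate:** population structure and admixture,
genotype imputation uncertainty, non-MCAR missingness, batch effects, and
assay floor/ceiling effects. Tests passing on these cohorts demonstrate the
correctness and calibration of the machinery, not performance on real
cohorts.

## Preprocessing

Variant QC removes variants with ≥ 5% missing calls (call rate ≤ 0.95),
minor allele frequency < 0.05 (strict inequality: MAF exactly 0.05 is
retained), or an exact Hardy–Weinberg p-value < 0.001. The HWE test is the
conditional exact test on the heterozygote count (not mid-p), computed on
the log scale and verified against a full-enumeration oracle. The three
filters commute, so QC is order-invariant.

Traits entering GWAS are residualized on sex, age, BMI, the seasonal
encodings, cell counts (and, in the standalone GWAS path, the first three
genotype principal components), then inverse-rank normalized with the Blom
offset c = 3/8 — the offset is a package choice; the transform is otherwise
standard. Prediction features are z-scored with parameters estimated on the
training split only and reapplied to the test split.

## Association testing

Univariate GWAS is per-variant simple linear regression of the adjusted
trait on dosage (two-sided t test, n − 2 df), vectorized across variants
with per-variant complete cases; monomorphic variants yield missing results.
The multivariate test targets a *cytokine network* — the central trait plus
all traits with |Pearson r| > 0.2 against it — and tests each variant
against the linear combination of member traits maximizing the correlation
with the dosage. For one variant against q traits the squared canonical
correlation equals the R² of regressing the dosage on the traits, so
Wilks' λ = 1 − ρ² and F = ((n−q−1)/q)·ρ²/(1−ρ²) with (q, n−q−1) df is exact
in this rank-1 case; loadings are the unit-norm coefficient vector with the
largest-magnitude element made positive (the sign is otherwise arbitrary).
Lead SNPs are selected greedily below 5×10⁻⁸ with a ±500 kb exclusion
window; λ_GC is the median association χ² over its null median.

## Clumping + thresholding prediction

`clump()` implements greedy LD clumping by ascending p-value: variants with
p < p1 seed clumps; unassigned variants with p < p2, within 250 kb on the
same chromosome and with r² > 0.5 against the index (r² computed in-sample
from the selection cohort's dosages) join and are discarded. The defaults
(p1 = 1e-5, p2 = 1e-2) are the reference protocol. The C+T score is the
plain sum Σ β × effect-allele dosage over index variants — rank-based
evaluation is invariant to positive scaling, so sum versus per-allele mean
is immaterial. Allele matching is strict: effect allele equal to ALT uses
the dosage, equal to REF uses 2 − dosage, anything else is skipped and
logged (strand flips are never guessed; silent strand guessing corrupts
scores). Missing dosages contribute the variant's mean dosage.

## Benchmark protocol and the leakage experiment

`run_benchmark()` runs, per outer fold of a 5-fold plan: GWAS-based marker
selection on the *selection cohort*, feature assembly, optional random
hyperparameter search (25 configurations, internal 5-fold CV on the
training split), fitting, and test-fold Spearman evaluation. Under
`TRAIN_ONLY` the selection cohort is the training split; under
`FULL_COHORT` it is everyone including the test fold — the data-leaking
scenario. An audit log records the individual IDs touched by each stage;
tests assert that in `TRAIN_ONLY` mode the selection and test sets never
intersect, and that the two arms of `leakage_experiment()` differ *only* in
the selection cohort.

Model kinds: `ct` (the untrained C+T score), `ols`, `ridge`, `en`
(glmnet), `rf` (ranger, 500 trees), `gbt` (xgboost), and `ann` — a
multilayer perceptron written in-package (Adam optimizer, ReLU hidden
units, L1/L2 penalties, early stopping on a 10% validation split with
patience 10, at most 200 epochs) because no installed R learner supports
the full 1–3-hidden-layer grid. All learners are deterministic given a
seed and tolerate p > n.

When a fold's training GWAS selects no variant, the genetic feature set is
empty: C+T emits a missing result and learners fall back to intercept-only
predictions rather than silently relaxing p1. Benchmark summaries count
such missing fold correlations as zero rank skill, which keeps
genetic-versus-combined comparisons honest for environment-dominant traits.

**Desk-scale calibration.** The reference protocol selects markers from a
genome-wide panel (~5×10⁶ variants) at p1 = 1e-5 — about 50 expected
selections under the null. At the desk scale used in replicated experiments
(≤ 5,000 variants) the same expected selected-marker count requires
p1 = 1e-2, so those experiments pass `clump_params(p1 = 1e-2, p2 = 1e-2)`;
single-run analyses keep the reference defaults. Replicated experiments
also use the fixed per-kind default configuration instead of the 25-config
random search, and evaluate permutation importance on the first one or two
cross-validation folds (`importance_folds`), bounding the
forest-prediction cost of 10-seed experiments on one CPU; the paired
train-only/full-cohort comparison is unaffected because both arms share
folds and seeds. Single-fold importance of a null trait is noisy — with
5-fold averaging the leakage importance delta is positive in every seed we
examined, with one fold it is positive in 8 of 10.

## Evaluation machinery

Spearman correlations use average ranks and a t approximation for p.
Model-by-trait performance matrices are compared with a tie-corrected
Friedman test (cross-checked against `stats::friedman.test`), Conover
post-hoc t statistics on rank sums with Holm step-down, and grouping of
statistically indistinguishable models as connected components of
non-rejected pairs — the critical-difference-diagram convention.
Permutation importance permutes one test-set feature column at a time,
re-predicts, and reports the mean drop in test Spearman over 50
permutations; all selected variants aggregate into a single "SNPs" category
by summing member scores (an optional joint-block permutation mode exists
for sensitivity analysis and is not the default). Importance is reported as
raw Δρ, not normalized.

## Phenotype imputation

`soft_impute()` is nuclear-norm-regularized matrix completion: missing
cells start at zero; each iteration soft-thresholds the singular values of
the current completion by λ and restores observed cells, until the relative
Frobenius change of the missing block falls below 1e-5 (tolerance and the
500-iteration cap are package choices) — the penalized objective is
non-increasing across iterations and observed cells are never modified.
λ is tuned on the grid σ₁/K, K ∈ {1.5, 2, 4, 10, 50, 100} (σ₁ = largest
singular value of the zero-filled matrix) by repeatedly masking one
observed value per column and minimizing the mean MSE on the masked cells;
the default 100 repeats is a desk-scale choice, the reference protocol's
1000 is a flag away. Individuals missing more than 80% of their panel are
excluded first. Imputed values feed *only* association analyses; prediction
models use complete cases exclusively. Accuracy is summarized by the RMSE
skill score 1 − RMSE_model/RMSE_mean per column.

## Immunotype discovery

Individuals are clustered on inverse-rank-normalized cytokine responses
with Euclidean Ward agglomerative clustering (Ward for individuals; average
linkage is the convention for reordering trait-correlation heatmaps), k
from 2 to 15, scored by average silhouette and by the gap statistic with
B = 100 reference datasets drawn uniformly over each feature's observed
range and passed through the same normalization as the data. Because
inverse-rank normalization maps any sample onto fixed normal quantiles, the
k = 1 dispersion of data and references coincide (gap₁ = 0); the gap
*increase* from k = 1 to k = 2 remains the informative signal, and the
standard 1-SE selection rule is reported alongside the full curve without
overriding the silhouette choice. Cluster differences are tested per
variable — Mann–Whitney U for continuous, chi-square without continuity
correction for categorical (Kruskal–Wallis beyond two clusters) — with
Bonferroni adjustment.

## Polygenic scores

`apply_pgs()` scores PGS-Catalog-style weight files with the same strict
allele-matching rule as C+T and reports matched/flipped/skipped counts.
PGS–cytokine associations are tested against a permutation null: the trait
is permuted 1,000 times and the two-sided empirical p is
(1 + #{|ρ_perm| ≥ |ρ_obs|})/(n_perm + 1) — the +1 convention keeps p ≥
1/1001 and maps the "< 5% of the null" significance rule to p < 0.05. By
default the raw trait is used; pass covariate-adjusted values for an
adjusted analysis. `pgs_as_features()` appends standardized PGS columns to
a feature table so the benchmark and importance machinery apply unchanged.

## Numerical choices and degenerate inputs

Ties in p-value orderings break by (chromosome, position, ID). Constant
vectors make Spearman and inverse-rank normalization undefined (missing
result with a warning, or an error, respectively). Zero-variance features
are dropped by the scaler with a warning. The HWE test uses a 1e-10
relative tolerance when comparing configuration probabilities, so
probability ties are included as in the standard exact test. Residualization
refuses rank-deficient covariate matrices and names the collinear columns.
The permutation importance of a constant column is exactly zero (its
permutation is the identity).

## Problem sizes used in the shipped tests

Oracle-equivalence tests run on hundreds of small random instances (≤ 50
variants, n ≤ 200). Calibration tests use n = 400–2,000 individuals and
2,000–5,000 variants; the leakage experiment uses n = 400 with
5,000 null variants and 10 seeds; the importance-dichotomy and
added-value experiments use the default 2,000-variant panel, n = 400, 10
seeds. These sizes were chosen so the full suite runs on a single CPU in
well under half an hour while leaving every qualitative conclusion
(leakage inflation, the TCR/TLR importance dichotomy, the added value of
combined features) clearly resolved.

## Known limitations

The MV-GWAS is exact only in the single-variant (rank-1) case, which is the
only case the pipeline uses. The MLP is a minimal implementation — adequate
for the benchmark contract, not a deep-learning framework. The generator's
environmental covariates are mutually independent, which real cohorts are
not; correlated covariates would make permutation importance scores
share credit. Cross-cohort validation assumes the second cohort measures
the same covariates; hormone levels are deliberately excluded from its
default feature list.
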