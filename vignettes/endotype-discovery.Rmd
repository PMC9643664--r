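---
title: "Discovering blood-transcriptome endotypes across cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering blood-transcriptome endotypes across cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fibrotype` implements a complete discovery-and-validation workflow for
molecular subgrouping of idiopathic pulmonary fibrosis (IPF) from pooled
blood gene-expression cohorts: controls-anchored co-normalisation, consensus
clustering with an optimality map, a compact greedy gene classifier, up/down
signature risk scoring, and a survival/clinical statistics layer. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the methodology was genuinely open.

## The problem

IPF is clinically heterogeneous: some patients progress slowly, others die
within a couple of years. If that heterogeneity reflects distinct
pathophysiological mechanisms (endotypes), unsupervised structure in blood
transcriptomes should separate patients into groups with different outcomes.
No single public cohort is large enough, so cohorts profiled on different
platforms must be pooled — which demands removing technical (batch)
differences without erasing biology.

## Controls-anchored co-normalisation

Cohorts are pooled on the intersection of their gene panels
(`intersect_and_pool()`). Batch adjustment follows the ComBat location/scale
model, but every parameter is estimated from **healthy controls only**
(`fit_control_combat()`), because case/control composition differs across
cohorts and cases may legitimately differ between cohorts. The identifying
assumption is that healthy controls in all cohorts are draws from one
statistical distribution, so *any* systematic control difference between
cohorts is technical.

Per gene $g$: $\alpha_g$ is the mean over all controls and $\sigma_g$ the
pooled *within-batch* control SD. Controls are standardised,
$z = (x - \alpha_g)/\sigma_g$; per batch $b$ the raw location and scale
effects are the control mean $\hat\gamma_{bg}$ and variance
$\hat\delta^2_{bg}$ of $z$. Parametric empirical-Bayes priors
($\gamma_{bg} \sim N(\bar\gamma_b, \tau^2_b)$,
$\delta^2_{bg} \sim \text{InvGamma}(\lambda_b, \theta_b)$, hyperparameters by
method of moments across genes) are combined with the standard ComBat
fixed-point updates until the largest change falls below `tol` (default
1e-4, `max_iter` 100). Every sample of batch $b$ — cases included — is then
adjusted as

$$y = \sigma_g\,\frac{(x-\alpha_g)/\sigma_g - \gamma^*_{bg}}{\sqrt{\delta^{2*}_{bg}}} + \alpha_g .$$

Design notes:

* $\sigma_g$ must be the pooled **within**-batch SD. Folding between-batch
  offsets into the scale inflates $\sigma_g$, which then deflates
  $\hat\delta^2$ and re-inflates every case-control contrast on adjustment;
  we observed exactly this distortion with the naive pooled SD.
* EB shrinkage means adjustment is not exactly idempotent: a refit on
  adjusted data still sees the small shrinkage residual
  $\hat\gamma - \gamma^*$. Re-application is a strong contraction (the
  second pass moves values by under a tenth of the first), and the tests
  assert that property rather than exact idempotence.
* `min_controls = 3` per batch; genes whose control variance is below 1e-8
  in any batch cannot be standardised and are dropped with a warning.
* After adjustment, controls are removed from all downstream analysis.

`batch_mixing_score()` quantifies the Figure-style diagnostic: the ratio of
between-batch centroid dispersion to total dispersion in the first two
principal components (0 = perfectly mixed, towards 1 = fully separated).

## Consensus clustering and the optimality map

`run_grid()` clusters the co-normalised cases with two algorithms — k-means
(20 random restarts) and PAM — over a grid of cluster numbers `k_values` and
gene-subset sizes `gene_counts` (most-variable genes, z-scored, Euclidean
distance). Five validity indices are computed per cell: average silhouette
width, Dunn index, Calinski-Harabasz, connectivity (Handl et al.;
sign-flipped so higher is better), and the gap statistic (Tibshirani;
uniform reference sets over the range of each standardised feature, `gap_B`
draws shared across k and algorithms per gene ladder).

`build_optimality_map()` z-scores each index across all successful cells,
averages the five z-scores per cell and the two algorithms per (k,
gene-count), and picks the maximising cell, with ties broken toward smaller
k and then fewer genes — favouring the more parsimonious description when
the evidence is equal. The gap statistic's standard-error rule is reported
but not used for selection, so that all five indices enter selection the
same way.

`consensus_assign()` matches PAM labels onto k-means labels by
maximum-agreement one-to-one matching (Hungarian algorithm over the k×k
contingency table; exact, and verified in tests against exhaustive
permutation search). Samples on which the matched algorithms disagree are
called UNCLUSTERED and excluded downstream — the price of only keeping
samples whose assignment is algorithm-robust.

## The greedy cluster classifier

To carry cluster membership into cohorts that lack controls (and hence
cannot be co-normalised), `derive_candidate_genes()` screens genes per
cluster (one-vs-rest Welch tests, Benjamini-Hochberg FDR `alpha_fdr = 0.01`,
absolute mean difference at least `min_effect = 0.5` log2 units), and
`greedy_train()` builds a compact up/down signature: the score of sample $s$
for cluster $c$ is the mean within-dataset z-scored expression over $c$'s up
genes minus the mean over its down genes, and the predicted cluster is the
argmax. Genes are added one at a time — whichever candidate most increases
cross-validated balanced accuracy (stratified folds, seeded) — until the
gain drops below 0.001 or `max_genes = 30` genes are used. Within-dataset
z-scoring makes the score invariant to any affine transform of a cohort's
expression scale, which is what lets one classifier travel across
platforms; this is also why validation cohorts are deliberately *not*
co-normalised with the discovery data.

A note on honesty of the reported accuracies: the signature has no fitted
weights, so cross-validation here guards against selection (which genes) not
estimation; `cv_accuracy` is reported alongside the refit
`training_accuracy` and tests assert the two stay close.

## Risk scoring and method comparison

`sams_score()` implements the up/down-signature scoring used by molecular
subphenotype classifiers: per sample, the mean z-score over the signature's
up genes minus the mean over its down genes, dichotomised at the cohort
median (ties to low risk). The exact thresholding rule of the original
publication is in its own supplement, so the median split is a documented
default isolated in one function. Missing signature genes are dropped with a
warning provided any remain. `method_agreement()` is the percent of samples
with equal risk calls. For survival comparisons the cluster classifier is
dichotomised with one low-risk cluster — the one with the best observed
survival (smallest events-per-person-time) in training data, recorded in the
classifier — and all other clusters counted as equally high risk.

## Statistics layer

`compare_traits()` routes each trait the way clinical tables are built:
chi-square for count data (Fisher's exact test when any expected cell is
below 5), one-way ANOVA for continuous traits with overall sample skewness
$|g_1| \le 1$, Kruskal-Wallis otherwise, and the k-group log-rank test for
time-to-event data; missing values are dropped per trait with the used n
reported. `gap_index()` scores the published gender-age-physiology table
(0-8 points). Survival uses the `survival` package: Kaplan-Meier curves with
medians by the smallest-time-with-$S(t)\le 0.5$ convention, Cox
proportional-hazards fits with Efron tie handling, Harrell's C with a
Noether-type CI, and nested likelihood-ratio tests on identical record sets.
Monotone likelihood (separation) and zero-event fits are refused with
errors rather than returning unstable estimates.
`ora_hypergeometric()` provides a generic upper-tail hypergeometric
over-representation test against user-supplied gene sets with BH adjustment
(pathway databases themselves are out of scope).

## The synthetic study generator

`simulate_multi_cohort()` generates the ground-truth world every stage is
tested against:

* baseline $\mu_g \sim N(8, 2)$ on the log2 scale, residual noise SD 1;
* per batch × gene, additive offsets $\gamma_{bg} \sim N(0, 2)$ and
  multiplicative variance factors
  $\delta^2_{bg} \sim \text{InvGamma}(5, 4)$ (mean 1, factor SD ≈ 0.3) —
  deliberately the ComBat generative form, so parameter recovery by the
  co-normalisation stage is a meaningful test, not a tautology;
* K = 3 latent case subgroups in proportions 0.33/0.48/0.19 with disjoint
  150-gene signatures, shifted ±1.5 noise-SD units (directions random);
  controls carry no subgroup signal;
* exponential survival with hazards 0.25/0.08/0.30 per year (the middle
  subgroup is the low-risk one) and exponential censoring at rate 0.10;
  a Weibull shape is exposed for non-constant hazards, with the default 1
  keeping closed-form oracles (the exponential rate-ratio MLE) available;
* clinical covariates: age ~ N(67, 8), 70% male, FVC/DLCO/FEV1 percent
  predicted with subgroup shifts that give the low-hazard subgroup
  relatively preserved lung function; an optional masking flag hides ~20% of
  lung-function and genotype values to emulate partially reported tables;
* partially overlapping platforms: a configurable fraction of genes is
  designated common to all cohorts; each cohort keeps a random private
  subset of the rest, with the guarantee that the panel intersection equals
  the designated common set.

Cohort sizes default to cases 70/93/57 with controls 45/30/20 (discovery)
— the scale of the pooled public study design this emulates — and
validation runs reuse an existing truth (same genes, signatures,
directions) while drawing fresh batches, samples and survival.

What the generator does **not** emulate: probe-level microarray artefacts,
count noise of RNA-seq, realistic gene-gene correlation beyond the planted
signatures, non-proportional hazards, and informative censoring. Passing
tests therefore demonstrate correctness of the machinery and recoverability
under the stated model, not performance on any real cohort.

## Numerical choices and degenerate inputs

* EB fixed point: `tol = 1e-4`, `max_iter = 100`, with degenerate priors
  (zero across-gene variance, e.g. a single batch) falling back to the raw
  estimates instead of dividing by zero.
* Clustering: genes are z-scored before distances; constant rows map to
  zero. Grid cells that fail (degenerate submatrix, empty k-means cluster)
  are marked failed and excluded from the map rather than aborting the run.
* Ties: argmax classification ties go to the lowest cluster index; risk
  ties at the median go to low risk; optimality ties to smaller k then
  fewer genes; variable-gene ties to lexicographic gene id.
* Seeds: every stochastic step (simulation, k-means restarts, gap
  references, CV folds) derives its stream from one user seed; reruns are
  byte-identical, which the pipeline manifest (MD5 per artifact) makes
  checkable.

## Problem sizes used in tests and the acceptance script

The shipped tests and `scripts/acceptance.R` run the full pipeline at desk
scale, chosen so the whole suite completes in minutes on one core while
every property is still sharply testable: simulations of 1000-2000 genes
with 150-300 cases across 2-3 cohorts, clustering grids over k = 2..5 and
gene ladders 100/250/500, gap statistic with 20-30 reference draws (50 is
the package default), and survival simulations of 500-2000 subjects with
500 replicates for calibration checks. The acceptance script mirrors the
study design proper: 220 discovery cases + 95 controls in three cohorts,
194 validation cases in three cohorts.

## Known limitations

* The co-normalisation assumes exchangeable healthy controls; confounded
  control differences (age, sex imbalance between cohorts) would be removed
  as if technical. No covariate-adjusted or reference-batch ComBat is
  provided.
* Only k-means and PAM are built in; model-based and hierarchical
  clustering, and Monti-style bootstrap consensus matrices, are out of
  scope.
* The classifier's within-dataset z-scoring needs a reasonably sized,
  reasonably representative validation cohort; it will mis-scale on tiny or
  heavily case-enriched subsets.
* The SAMS-style median split forces half of each cohort into each risk
  group; when the truly high-risk subgroup is a minority, that dilutes its
  hazard ratio — visible in the synthetic validation run, where the
  signature method under-stratifies relative to the cluster classifier.
* Survival machinery assumes proportional hazards and non-informative
  censoring; no competing risks or time-varying covariates.
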