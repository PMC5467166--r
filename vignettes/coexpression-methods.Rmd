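---
title: "Methods: co-expression modules, trait association and causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, trait association and causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comod)
```

This vignette is the package's own account of the methods it implements:
the model assumptions, the tunable parameters and their defaults, what the
synthetic cohort does and does not emulate, and the numerical and design
choices made where the method itself leaves room.

## The weighted co-expression network

The input is a genes × samples matrix of log2 expression values. The
network is *unsigned*: similarity is the absolute Pearson correlation
`s_ij = |cor(x_i, x_j)|`, so strongly anti-correlated genes are treated as
co-expressed. Soft thresholding raises similarity elementwise to an integer
power β, `a_ij = s_ij^β`, which suppresses weak chance correlations without
imposing a hard cutoff. The diagonal of every matrix is stored as 1
(similarity, adjacency, topological overlap) or 0 (dissimilarity), and
connectivity `k_i = Σ_{j≠i} a_ij` always excludes the self-edge.

β is chosen by the scale-free topology criterion: for each candidate power,
connectivities are binned into 10 equal-width bins, the empirical frequency
p(k) and mean k of each non-empty bin are computed, and log10 p(k) is
regressed on log10 k. `pick_beta()` returns the smallest power in the grid
(default 1–12) whose R² reaches 0.8, the threshold conventional for this
criterion; if none qualifies, the best-fitting power is returned with a
flag rather than an error, because a mis-specified grid should be visible,
not fatal. The R² of this fit is invariant to rescaling all connectivities
(a log-log shift), so whether p(k) is a frequency or a density does not
change the selection; the reported slope estimates the negative power-law
exponent under the frequency convention used here.

Topological overlap measures shared neighbourhood rather than direct
adjacency:

`ω_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
`ℓ_ij = Σ_{u≠i,j} a_iu a_uj`, `ω_ii = 1`.

The implementation computes ℓ via one dense matrix product and corrects the
two diagonal terms, then symmetrizes to remove floating-point asymmetry;
the test suite verifies exact (1e-12) agreement with a brute-force
triple-loop oracle on random matrices. Dense matrices cap the problem size:
`compute_similarity()` refuses more than 20,000 genes unless the cap is
raised explicitly.

## Module detection

Modules are cut from the average-linkage hierarchical clustering of
`d_ij = 1 − ω_ij`. Two departures from a naive fixed-height cut deserve
explanation, because they are where this implementation makes genuine
choices:

1. **Adaptive cut height.** After soft thresholding at the scale-free β,
   dissimilarities concentrate in a narrow band near 1 (with β around 8,
   within-module dissimilarities sit at ~0.998 and between-module ones at
   ~0.99999), and the informative band moves with β and with the data.
   A fixed absolute height is therefore not transferable across data sets;
   on simulated cohorts with known modules a fixed cut at, say, 0.95
   recovers nothing. The default `cut_height = "auto"` instead scans the
   merge-height midpoints of the dendrogram and cuts at the lowest height
   that maximizes the number of clusters reaching `min_module_size`
   (default 30). This is reproducible, deterministic, and reduces to the
   obvious answer on clean block structure. A numeric `cut_height` remains
   available as the static option.

2. **Eigengene (kME) refinement.** A dendrogram cut leaves boundary errors:
   genes attached to the wrong branch, background genes chained into a
   module. `refine_modules()` iteratively recomputes module eigengenes and
   reassigns every gene to the module whose eigengene it best correlates
   with, dropping genes whose best |kME| is below 0.3 to the background,
   until labels stabilize (at most 5 sweeps). On the default synthetic
   cohort this raises the adjusted Rand index against the planted labels
   from roughly 0.5–0.8 (cut alone) to 0.95–0.98. The 0.3 threshold is the
   conventional "weak membership" boundary for standardized expression; it
   was fixed once, during method design on simulated data, and is exposed
   as a parameter.

The module eigengene is the first right singular vector of the module's
row-standardized expression (zero mean, unit Euclidean norm across samples),
with `variance_explained` the first squared singular value over the total.
Standardizing first makes the summary scale-free: a highly expressed gene
does not dominate. The sign of a principal component is arbitrary, so the
eigengene is aligned to correlate positively with the mean standardized
member profile; in the degenerate case where that profile cancels exactly
(e.g. a module consisting of x and −x) the sign is aligned to the first
member gene, deterministically, and `sign_flipped` records whether the raw
SVD sign was reversed.

## Trait association

`associate_eigengene_trait()` fits logistic regression for binary traits
and linear regression otherwise, reporting the Wald beta and p of the
eigengene term. Three conventions matter:

- Insulin-secretion traits (columns named `secretion_*`) are
  log-transformed before fitting, because secretion measures are strictly
  positive and right-skewed; as a consequence the association is invariant
  to the measurement unit (a multiplicative rescaling moves into the
  intercept), which the tests assert.
- The eigengene is standardized to unit SD by default, so betas are
  per-SD effects comparable across modules and to latent-factor effect
  sizes; `standardize = FALSE` restores the raw unit-norm scale.
- Covariate adjustment (age, sex, BMI by default in the pipeline) and
  sample filters are orthogonal options: a filter is any predicate on the
  phenotype table (e.g. non-diabetic donors with BMI above the median of
  the analyzed subset), evaluated before the model is fitted; at least 10
  samples must remain. One-sided p-values (used for replication-style
  hypotheses with a known direction) halve the Wald p when the estimate
  has the hypothesized sign and report `1 − p/2` otherwise.

Logistic fits that separate completely are flagged (`converged = FALSE`)
rather than returned as silent, divergent estimates. Both adjusted and
unadjusted associations are written by the pipeline, since either may be
the relevant headline number.

## Enrichment and hub statistics

Gene-set overlap uses the exact hypergeometric upper tail (one-sided, the
default) or the two-sided Fisher convention of summing tables no more
probable than the observed one. Ids absent from the universe are dropped
with a warning instead of an error — annotation mismatches between
platforms are the norm, and silently erroring on them helps no one. The
result carries the full 2×2 counts, the odds ratio, the fold enrichment
(observed over expected overlap, expected = set × target / universe), and
the capture fraction (share of the set inside the target), which is the
number quoted when one says a module "captures 49%" of a gene set.
`bh_adjust()` applies the standard step-up false-discovery-rate correction
across a family of such tests.

Comparing connectivity between a gene set and its module background is
under-determined — connectivity is continuous, a Fisher test wants a 2×2
table. The implemented reading dichotomizes `k_in` at the pooled median and
applies a one-sided Fisher test of set membership against above-median
connectivity; a Wilcoxon rank-sum alternative is exposed for users who
prefer not to dichotomize. The reported effect size is the ratio of mean
connectivities, which is well-defined either way.

The resampling region-enrichment statistic (for motif-in-promoter style
counts produced outside this package) pools all random region sets into a
single background proportion and applies a one-tailed Fisher test; pooling
is the implemented default because it uses every resample, and an
alternative per-resample empirical p (share of random sets at least as
hit-rich, add-one smoothed) is returned alongside for those who prefer the
resampling distribution itself.

## Differential signatures and concordance

`build_signature()` computes per-gene log2 fold changes as group mean
differences on the log2 scale (equivalently the group coefficient of a
per-gene linear model when covariates are supplied) with ordinary
least-squares p-values — deliberately not moderated/empirical-Bayes
statistics, which are out of scope. Directional concordance between a test
signature and a reference counts, among set genes differentially expressed
in the test at nominal p < α (default 0.05), those changing in the
reference direction; enrichment of concordant-DE genes in the set relative
to the background is a one-sided Fisher test, and a binomial test against
0.5 is also reported since "more than half concordant" is the other natural
null. The consistent-responder analysis (same direction as the reference
under knockdown, opposite under overexpression, both at p < α) tests the
observed qualifying count among doubly-DE genes against the 1/4 probability
of that sign pattern under independent random directions — a binomial
construction, since no 2×2 table exists against a theoretical rate.

Cross-platform intensity detrending fits a B-spline (default 8 degrees of
freedom) of a sample's per-gene means on reference means and returns
residuals re-centred on the reference; the variance scan compares a
signature's mean per-study variance against same-size random gene sets
(add-one-smoothed empirical p, seeded).

## The causal inference test

For a categorical dose L (levels 0 / 0.1 / 1 by default, used numerically
only for reporting betas), mediator G and outcome T, the causal omnibus
p-value is the maximum of four component p-values (an intersection-union
test — every condition must hold):

1. `p1`: F-test of L in `T ~ L` — the dose moves the outcome.
2. `p2`: F-test of L in `G ~ L + T` — the dose moves the mediator beyond
   what the outcome explains.
3. `p3`: F-test of G in `T ~ G + L` — the mediator carries information
   about the outcome beyond the dose.
4. `p4`: an equivalence-type test that T is *independent* of L given G.
   Small p4 is evidence for conditional independence. The null of "a
   direct dose effect remains" is materialized by permutation: regress G
   on L, keep the fitted dose means, permute the residuals. This severs
   mediation while preserving the dose–mediator association, so under the
   permuted data L must explain the outcome directly; p4 is the
   add-one-smoothed fraction of permuted conditional F statistics (for L
   in `T ~ G* + L`) that fall at or below the observed one.

The reactive omnibus repeats the construction with G and T exchanged, and
the same permutation indices are reused, so exchanging the roles of G and
T swaps the two omnibus values exactly — an identity the tests assert.
Verdicts compare both omnibus values to α = 0.05: causal, reactive,
independent (neither), or undecided (both). Simulation at n = 300 with 500
permutations shows power ≈ 1 under the planted causal model, type-I error
≈ 0 under independence (the maximum of four p-values is conservative), and
near-perfect discrimination of reactive from causal chains; these rates
are recomputed by the acceptance script, not quoted from anywhere.

Defaults: 1000 permutations (100 is the warning floor), seed mandatory in
spirit — every permutation is derived from the `seed` argument, so results
are bit-reproducible.

## The synthetic cohort generator

`generate_cohort()` draws a planted factor model: module m has a latent
factor `e_m ~ N(0,1)` per sample; member genes load on it with coefficient
0.8 (default), plus Gaussian noise with SD 1 on the log2 scale; a labelled
subset (20% of each module by default) loads at 0.8 + 0.2, emulating a
hub-like gene set with elevated intramodular connectivity. Defaults mirror
the shape of a 64-donor islet cohort with ~19 diabetic donors and five
50-gene modules among 300 genes; the module count and sizes are scale
emulation, not biology. Traits are generated from the factors: T2D status
via a logistic model (baseline prevalence 19/64, default log-odds effect
1.5 per SD of module 1's factor), HbA1c linear around 5.7% (effect 0.4,
noise SD 0.5), and two secretion measures log-linear in the factor, so the
log-transform convention downstream is exercised. Age, sex and BMI are
independent nuisance covariates (sex balanced binary with no effect, BMI ~
N(27, 4²) so median splits are meaningful). The expression variance
structure of real islet cohorts is unknown to us; these are free,
documented parameters, fixed once, not estimates of any data set.

What the generator does *not* emulate: probe-level artifacts, batch
effects, missing values, heavy-tailed expression noise, correlated
covariates (age–BMI–disease), or overlapping/nested modules. Passing tests
on this generator therefore demonstrate the pipeline's correctness and
calibration under its stated assumptions, not robustness to real
microarray pathology.

`generate_perturbation_signature()` assigns each reference-covered gene the
reference direction with probability c and the opposite direction otherwise
(so the measured concordant fraction estimates c directly, which the tests
exploit across c ∈ {0, 0.25, 0.5, 0.75, 1}); `flip` models an
opposite-acting perturbation. Significance is planted in a fraction
`alpha_frac` of genes and magnitudes are LogNormal(−0.5, 0.5).
`generate_cit_triplet()` plants the three causal scenarios with balanced
dose assignment.

## Problem sizes and runtime

The test suite and acceptance script run at the default study shape:
10-seed module recovery, 100-cohort trait-effect recovery, 50-seed hub
comparisons, and 100 runs × 3 scenarios × 500 permutations for the causal
inference test (n = 300). These sizes give binomial margins comfortably
inside the asserted bounds and complete in well under a minute of compute
each; they are the package's chosen simulation sizes, stated here so that
anyone re-running the suite knows what was actually computed.

## Known limitations

- Static and auto cuts both operate on a single dendrogram; dynamic
  tree-cut variants (adaptive branch shape criteria) are a documented
  extension point, not implemented.
- No signed networks, biweight midcorrelation, or block-wise approximation
  for very large gene counts.
- Module merging by eigengene correlation and consensus modules across
  cohorts are out of scope; cross-cohort replication is handled as overlap
  enrichment.
- The causal inference test addresses one trio at a time; multi-mediator
  models and FDR across many trios are out of scope.
- The per-gene differential expression is unmoderated ordinary least
  squares; with very few replicates per group its variance estimates are
  noisy by design.
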