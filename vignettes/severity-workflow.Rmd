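---
title: "Composite measure schemes for severity assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite measure schemes for severity assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevcms)
```

## The problem

Severity assessment asks how much distress an individual laboratory
animal experiences under a given procedure or genetic model. No single
behavioral or biochemical readout captures this reliably: home-cage
behaviors (burrowing, nest building), clinical scores (Irwin),
open-field measures, anhedonia proxies (saccharin preference) and
stress-hormone readouts (fecal corticosterone metabolites) each reflect
a different facet, each with its own noise, missingness and
redundancies. A composite measure scheme (CMS) treats the battery as a
multidimensional measurement and derives (i) a stability ranking of the
parameters that carry severity-related information, (ii) a scalar
composite severity score per animal, and (iii) ordered severity levels
with data-driven thresholds, so that groups and models can be compared
by their severity-level allocations.

`sevcms` implements this workflow end to end for tabular
animal × parameter data. This vignette records the model, its
assumptions, every tunable that matters, and the design decisions taken
where the procedure was genuinely open.

## Data model and preselection

A *parameter table* is a tibble with reserved metadata columns
(`animal_id`, `model`, `group`, `age_bracket`, `sex`); every other
column is a numeric parameter. Missingness is explicit (`NA`) and never
conflated with zero, because missingness fractions themselves drive
preselection. Tables from separate subprojects are combined by column
union; animals shared between subprojects (e.g. a common naive group)
are deduplicated by `animal_id`, with conflicting metadata treated as a
hard error rather than silent first-wins.

Preselection removes parameters, never animals:

* **Data integrity**: a parameter is removed when its missing fraction
  strictly exceeds `missingness_cut` (default 0.2). The boundary case —
  exactly 20% missing — is retained, reading the rule literally as
  "more than 20%". The fraction is computed over the combined table as
  given, not per model.
* **Manual exclusions** are config-driven, because the judgments behind
  them (injury risk, pilot-quality data, weight changes driven by
  altered appetite rather than distress) are not computable from the
  data. Every removal is logged with its reason and fraction, and
  `retained + removed` always accounts for the full input inventory.

## Correlation pruning

Redundant parameters would dominate a principal component analysis, so
highly correlated pairs are pruned first. Correlations are Spearman
coefficients on mid-ranks (tie-corrected), computed on
pairwise-complete observations — parameters have heterogeneous
missingness, and listwise deletion would discard most rows. Two-sided
p-values use the large-sample t approximation, replaced by exact
enumeration of all rank permutations when a pair has 8 or fewer
complete observations (at most 8! = 40 320 permutations). Pairs with
fewer than 3 complete observations or a constant member are flagged
undefined rather than propagated as `NaN`. No multiple-testing
correction is applied to the matrix by default — the cut-offs are raw
by design — but a Holm-adjusted variant is available
(`holm_adjust = TRUE`).

Flags use strict inequalities: *significant* means |r| > 0.5 with
p < 0.05, *redundant* means |r| > 0.7 with p < 0.05. Pruning then
repeatedly removes one member of some redundant pair until none
remains. The member to drop is chosen by an ordered preference list of
parameters to keep (`keep_rules`, e.g. preferring home-cage or
less-invasive assays), then by largest total |r| over remaining
redundant partners (so the hub of a redundancy chain A~B~C is removed
first, keeping both ends), then reverse-lexicographically for
determinism. Additional post-correlation exclusions (a
lower-sensitivity variant of a retained assay) are configuration
entries with a recorded reason.

## ROC screening

Discriminatory power is screened per parameter against a binary burden
classifier defined by the group mapping: 1 = with burden, 0 = without
burden, with non-implanted naive groups excluded because the classifier
contrasts intervention-with-burden against intervention-without-burden.
The AUC is computed by the rank identity
`(concordant + 0.5·tied) / (n_pos·n_neg)` (Mann–Whitney equivalence,
ties at 0.5), and the emitted ROC curve enumerates every distinct score
threshold; its trapezoidal area equals the rank AUC to numerical
precision, which the tests assert. Because a parameter may shift in
either direction under burden, both the directed AUC (larger score ⇒
burden) and the oriented AUC `max(AUC, 1 − AUC)` are reported, with a
flag when orientation was flipped.

## Normalization: shift, Box-Cox, standardize

Principal components are extracted from standardized, symmetrized
data. The transform order is: shift each parameter to strictly positive
support (`shift = 1 − min`, mapping the fit minimum to 1), apply a
Box-Cox transform with λ chosen by maximum profile log-likelihood on
the grid [−2, 2] in steps of 0.01, then center and scale to mean 0,
SD 1. Standardizing *before* Box-Cox is not well defined — the
transform requires positive input and centering produces zero-mean
data — so the package symmetrizes first and scales last, which
preserves the intent (symmetrize, then put all parameters on one
scale). The composed transform is strictly monotone per parameter. The
profile log-likelihood for the one-sample case is computed in closed
form, vectorized over the grid; the test suite cross-checks the
selected λ against an independent implementation.

Residual missing cells (at most 20% per parameter after preselection)
are imputed with the training-set median of the normalized parameter
before the decomposition; the imputation count is recorded. Applying a
fitted normalizer to data outside the fit range can produce values at
or below the positivity shift; these are clamped to a small positive
floor (0.5, half the fit minimum's image) so the transform stays
defined — a documented edge case that cannot occur on the fit rows
themselves.

## Resampled PCA ranking

The decomposition is the eigen-decomposition of the covariance of the
normalized matrix, components ordered by standard deviation, with a
deterministic sign convention (the largest-magnitude entry of each
loading vector is made positive). On fully standardized input the
squared component SDs sum to the number of parameters, which the tests
assert. Components with SD strictly greater than `sd_threshold`
(default 1) are selected — a component at exactly the threshold is
excluded.

The ranking procedure repeats, for each of `n_resamples` (default 100)
runs: draw a random `train_fraction` (default 80%) of the rows without
replacement, stratified by group (an unstratified draw can empty a
small group; stratification is recorded and can be disabled); fit the
normalizer and PCA on that subset; select components — per resample by
default, since the selection belongs inside the iterated procedure,
with `freeze_components = TRUE` offering a full-data frozen selection;
and rank parameters.

Two rank notions are recorded. Within each selected component,
parameters are ranked by absolute loading (rank 1 = largest); these
per-component ranks over every resample × component unit form the rank
histogram. The *primary* per-run rank, which orders the final ranking
table, ranks parameters by their **peak single-component variance
contribution** — the maximum over selected components of
eigenvalue × squared loading. This choice is deliberate: a parameter
that anchors one persistent strong component attains primary rank 1 in
essentially every resample, whereas averaging per-component loading
ranks across all selected components dilutes exactly the parameters
the procedure is meant to find (a parameter dominating one component
is, by orthogonality, unremarkable on the others, so its plain mean
rank is mediocre; empirically the plain mean failed to recover planted
parameters that the peak-contribution rank recovers in every seed).
Mean primary rank, best rank, top-1 and top-N membership counts over
runs, and the mean per-component loading rank are all reported;
`top_parameters()` emits the conventional top-30 table.

One behavior worth knowing: within a single dataset the resamples
share ~80% of their rows, so on structureless data the top-1 parameter
is "sticky" — the same incidental sample correlation wins repeatedly.
Uniformity under the null therefore holds *between* independent
datasets (the property the tests check), not within one dataset's
resample counts.

## Composite scores

Composite severity scores project all animals onto the reference
components (fitted on the full table), orient each selected component
so its score correlates non-negatively with the burden indicator
(larger = more severe; explicit `pc_signs` override this when no
burden labels exist), and combine the selected components. The default
`rank_sum` variant maps each animal's component score through the
mid-rank empirical CDF of the training scores — `(#below + 0.5·#tied)/n`,
so a training animal at the median contributes exactly 0.5 — and sums
over selected components, giving a score in (0, m] for m components.
The `score_sum` variant is the variance-weighted sum of oriented raw
component scores. Rank summation is the default because it is robust to
the heavy tails that remain after Box-Cox and makes scores comparable
across components.

## Severity clustering

Severity levels are a total order, so clustering operates on the
one-dimensional composite score (a `cluster-space` sensitivity variant
in component space would order clusters by mean composite score). In
one dimension the globally optimal k-means partition is contiguous in
sorted order, so `kmeans_1d()` finds the exact optimum by dynamic
programming over segment boundaries — no random initialisation, no
local optima; the tests verify it against exhaustive enumeration of
contiguous partitions and against 50 random-restart Lloyd runs.

The number of clusters comes from the configuration when set; a scree
elbow — the index maximising the second difference of the
explained-variance sequence — is always computed and recorded as a
suggestion. Cluster thresholds are the midpoints between adjacent
sorted centers, which reproduce nearest-center assignment exactly in
1-D. Robustness comes from resampling: the fit is repeated on
`cluster_resamples` (default 100) bootstrap resamples of the training
scores (bootstrap rather than subsampling because it yields percentile
confidence borders directly), and the model reports the per-boundary
resample mean and the 2.5/97.5 percentile interval at `ci_level`
0.95. Sorting the scores before resampling makes the procedure
invariant to input order under a fixed seed.

Assignment is deterministic: an animal with score s goes to cluster
`1 + #(thresholds ≤ s)` — a score exactly on a boundary goes to the
*higher* cluster, the conservative direction for a welfare
classification. Cluster k is the highest severity level. Allocation
tables report per-group (and per-model × group) percentages over
clusters, each row summing to 100, plus the combined share of the top
clusters (k and k−1 by default), which is the summary used to compare
burdened and control groups; a pooled mode counts animal × resample
units under every bootstrap threshold set instead of one modal
assignment per animal. Severity levels are relative to the models
analysed — the model output carries a disclaimer that they do not map
onto regulatory severity categories.

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` emulate the structure the
workflow assumes: several groups with planted standardized mean shifts
on a chosen informative subset of parameters, equicorrelated parameter
blocks built from a shared latent factor
(`x = √ρ·f + √(1−ρ)·e`, unit variance, within-block correlation ρ),
optional lognormal margins (specifically to exercise the Box-Cox
stage: rank-based quantities such as AUC and Spearman correlations are
unchanged by the exponentiation, while λ moves toward 0), and
completely-at-random missingness. The ground-truth object carries the
informative parameter names, the planted group severity ordering, the
realized missing mask and the closed-form expected AUC per parameter
(`Φ(d/√2)` for a normal shift d; mixtures of groups average the
pairwise values with size weights).

The standard validation conditions used throughout the tests are three
groups of 20 animals (control, intermediate, burdened), 15 parameters
of which 3 are informative with shifts 0 / 0.75 / 1.5 SD
(1.5 between the extreme groups), and an informative-block correlation
of ρ = 0.5. The block is part of the conditions by design: severity
parameters co-vary through the individual animal's latent severity
state, not only through group means — the paper-scale analogy is
inter-parameter correlations of roughly 0.5–0.8 — and ρ = 0.5 keeps
realized correlations below the 0.7 redundancy cut so pruning leaves
the informative set intact. Group shifts alone (no block) put the
severity factor near 27% of an informative parameter's variance, which
at 60 animals × 15 parameters sits below the sampling spread of noise
eigenvalues: a real detectability limit of the procedure, not an
implementation artifact.

What the generator does **not** emulate: informative missingness
(missingness is MCAR only), longitudinal structure, floor/ceiling
effects of bounded scores, sex or age interactions, and mechanistic
behavioral dynamics. Passing tests therefore demonstrate correctness
of the statistical machinery and recoverability of planted structure
under realistic noise — not that any particular real battery will
separate groups.

## Numerical choices and degenerate inputs

* Strict inequalities throughout (missingness > 0.2, |r| > cut-offs,
  SD > 1), matching the stated rules; boundary cases are tested.
* Constant parameters: a hard error in normalization (the transform is
  undefined); an undefined-flagged pair in correlation.
* PC sign convention (largest-|loading| entry positive) makes results
  independent of the linear-algebra backend's eigenvector signs.
* Per-stage seeds derive from the global seed and the stage name, so
  stages can be rerun independently yet reproducibly; identical
  input + config + seed reproduces every numeric output bit for bit.
* Ranking ties break by parameter name; pruning ties break
  reverse-lexicographically — both deterministic.
* Problem sizes in the test suite (60–100 animals, 10–15 parameters,
  100 resamples, 20 validation seeds) mirror the scale of multi-model
  severity batteries while keeping the default suite in the
  low-minutes range; closed-form eigenvalue checks use large n
  (10⁵–2·10⁵) where the comparison is against a population quantity.

## Known limitations

* Pairwise-complete correlation matrices need not be positive
  semi-definite; the matrix is used only for flagging pairs, never
  inverted.
* The t approximation for Spearman p-values is anti-conservative for
  very small n; the exact enumeration takes over at n ≤ 8, and the two
  agree within 0.05 at the boundary (tested).
* Median imputation before PCA shrinks variance slightly when
  missingness is substantial; preselection caps it at 20% per
  parameter.
* With fewer animals than parameters the covariance is rank-deficient;
  the decomposition still runs, but component selection and ranking
  stability degrade — the resampled ranking is the diagnostic.
* Severity clusters are relative to the analysed cohort. Comparing
  absolute severity across studies requires a shared reference cohort,
  which the method does not provide.
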