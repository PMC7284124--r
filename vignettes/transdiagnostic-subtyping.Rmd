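---
title: "Transdiagnostic subtyping of case-control cortical morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transdiagnostic subtyping of case-control cortical morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control comparisons of cortical structure in developmental disorders
(ASD, ADHD) are notoriously heterogeneous: a single decision boundary between
a pooled clinical group and neurotypical controls (NTC) averages over
subgroups that may deviate from controls in different — even opposite —
directions. `hydracluster` implements the HYDRA family of semi-supervised
discriminative clustering for this setting: instead of clustering patients by
mutual similarity (which happily picks up scanner, motion, or demographic
variation), it searches for $k$ subtypes *within the clinical group* such
that each subtype is separated from the controls by its own regularized
max-margin hyperplane. The $k$ hyperplanes form a convex polytope around the
control class; patients cluster by their *direction of deviation from
controls*, which is the pathophysiologically meaningful axis.

## The model

Given per-subject ROI features $x_i \in \mathbb{R}^p$ (cortical thickness in
mm or surface area in mm² averaged within each parcel of an atlas), group
labels (clinical/control), and an assignment of clinical subjects to
subtypes $S_1,\dots,S_k$, each polytope face $j$ is the weighted linear
hinge-loss (L1-SVM) problem

$$\min_{w_j,b_j}\; \tfrac12\lVert w_j\rVert^2
 + C\Big(\sum_{i\in S_j} \max(0, 1 - d_j(x_i))
 + \tfrac1k \sum_{i\in \mathrm{NTC}} \max(0, 1 + d_j(x_i))\Big),
 \qquad d_j(x) = w_j^\top x + b_j .$$

Every face sees *all* controls as its negative class, down-weighted by $1/k$
so that the control class does not dominate the total loss as $k$ grows. The
fitting objective is the sum of the $k$ face objectives, and the alternating
procedure is plain block minimization:

1. seed an assignment (below);
2. fit the $k$ faces for the current assignment;
3. reassign every clinical subject to $\arg\max_j d_j(x_i)$;
4. repeat 2–3 until the assignment is stable or `max_iterations` is hit.

A subtype emptied during reassignment is reseeded with the clinical subject
whose best decision value is lowest — the subject the current polytope
explains worst — which keeps the degenerate case deterministic.

The inner solver is a dual coordinate descent for the instance-weighted
hinge SVM (randomly permuted coordinate sweeps, augmented regularized bias),
written in C++. For the problem sizes this package targets (tens to a few
hundred subjects, $\le$ 400 ROIs) a single face fit takes well under a
millisecond, which is what makes cross-validated model selection and
permutation tests practical on one CPU.

### Initialization: directions, not labels

Block minimization of a non-convex objective depends heavily on its starting
point. Seeding restarts with uniformly random subtype labels turns out to be
a poor choice here: a random half of the clinical group has the *same* mean
deviation from controls as the other half, so the initial faces are nearly
parallel and the procedure stalls in shallow local optima. Each restart is
instead seeded from $k$ random clinical *deviation directions*: $k$ distinct
clinical subjects are drawn, their offsets from the control centroid act as
provisional face normals, and every clinical subject starts on the face of
largest projection. On planted-subtype benchmarks this raises the fraction
of restarts reaching the global basin from near zero to a majority, and the
restart objective correlates almost perfectly with recovery of the planted
labels (lower objective, better recovery), confirming that the objective —
not the optimizer — carries the signal.

### Consensus over restarts

`n_restarts` (default 20) seeded restarts are aggregated into a clinical ×
clinical co-assignment frequency matrix; consensus labels cut the
average-linkage tree of `1 − coassignment` into $k$ groups, and the polytope
is refit once from the consensus labels. One refinement: only restarts whose
objective lies within `consensus_trim` (default 10%) of the best restart
vote in the consensus. Shallow local optima otherwise blur the co-assignment
structure enough to destabilize fold-level solutions; with the trim, planted
two-subtype cohorts yield cross-validated ARI ≈ 1 at the true $k$. The
reported co-assignment matrix always covers all restarts, so the trim is
visible, not hidden.

## Choosing the number of subtypes

`cv_stability_sweep()` follows the stability logic used in the subtyping
literature: for each candidate $k$ (2–10 by default), the clinical group is
split into `n_folds` folds (10 by default); each fold's model is fit on all
controls plus the out-of-fold clinical subjects; and every pair of fold
solutions is scored with the adjusted Rand index on the clinical subjects
common to both training sets (plus the plain Rand index and an aligned
Hamming distance as secondary stability measures). The $k$ with the highest
mean ARI wins; ties go to the smaller $k$. With 2 folds the two training
sets share no clinical subjects, so each fold solution extends to held-out
subjects via the fitted polytope (`predict()`), and the single pair is
compared on the full clinical group — the only reading under which a 2-fold
sweep is defined at all.

Significance of the selected $k$ is assessed by `permutation_test()`: the
clinical/control labels — the supervised signal HYDRA consumes — are
shuffled across subjects (group sizes preserved), the mean CV ARI is
recomputed per shuffle, and the add-one p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$ is reported. Shuffling
*subtype* labels instead would be circular, since subtype labels are the
model's own output. The desk-scale default is $B = 199$; publication-scale
runs use 5000.

## The synthetic cohort generator

No raw data ship with this package; `generate_cohort()` produces cohorts
whose *design* mirrors the study the pipeline targets, with known ground
truth:

* 105 controls and 148 clinical subjects by default (99 ASD / 49 ADHD
  primary diagnoses, 13 dual-diagnosis), all-male adult cohort emulated only
  through its size and covariate ranges;
* 400 ROIs with baseline means drawn once per cohort from a cortical
  thickness–like range (1.5–4.5 mm); the fitted pipeline standardizes
  features, so this scale is cosmetic;
* residual noise `noise_sd` (default 0.15 mm, a realistic between-subject
  ROI-thickness SD); age acting linearly on all ROIs (default −0.005
  mm/year, garden-variety adult cortical thinning) and handedness acting on
  a random 10% of ROIs, so covariate adjustment has something real to
  remove;
* `n_subtypes` planted subtypes (default 2) shifted by
  `effect_size × noise_sd` on `affected_fraction` of ROIs (defaults 1.5 and
  0.3), with opposite signs on partially overlapping ROI sets — mirroring
  the inverse-pattern phenomenology that motivates polytope subtyping;
* diagnosis labels drawn independently of subtype by default (the null
  relationship the chi-square stage should report); a per-subtype
  `diagnosis_mix` plants an association for power checks.

What the generator does **not** emulate: spatial covariance between
neighbouring ROIs, site/scanner effects, non-Gaussian tails, heteroscedastic
ROI noise, or any vertex-level structure. Passing recovery tests on this
generator therefore demonstrates the estimator's correctness under its own
assumptions, not performance on real MRI-derived tables.

The atlas utilities treat parcellations abstractly: `generate_atlas_mapping`
partitions ROIs into seven resting-state-network labels, and
`generate_crosswalk` builds a row-stochastic ROI-overlap matrix by laying
both parcellations out as interval partitions of a one-dimensional cortex
coordinate (equal widths by default, so equal-sized atlases give the
identity and nested partitions give 0/1 rows). Real studies would substitute
measured overlap matrices; all downstream code consumes only the
row-stochastic contract.

## Downstream characterization

* `two_sample_tests()` — per-variable two-tailed Welch tests
  (pooled-variance behind a flag) with Benjamini–Hochberg correction
  applied within the family of variables of one call (all ROIs of one
  parameter, or one clinical-variable battery); families are never pooled
  across analyses.
* `chi_square_diagnosis()` — Pearson chi-square without continuity
  correction (Yates behind a flag) on diagnosis-by-subtype count tables.
* `anova_posthoc()` — one-way fixed-effects ANOVA across three diagnostic
  groups, Tukey HSD gated on the omnibus test.
* `conjunction_mask()` / `network_percentages()` — intersection of
  significant-ROI masks across analysis configurations and the percentage
  of each network altered. The denominator is the network size ("fraction
  of each network altered"); the complementary fraction-of-mask view is
  returned alongside.
* `project_mask()` — masks from a second parcellation are carried to the
  reference atlas through the crosswalk before intersection (threshold 0.5
  on summed overlap). How the original analyses merged two incompatible
  parcellations is not documented anywhere we could follow; the crosswalk
  projection is this package's choice and is labelled as such.
* `dice_membership()` — subtype memberships from two configurations are
  aligned by the overlap-maximizing label bijection (exhaustive; $k \le 8$)
  and summarized by per-subtype dice $2|A\cap B|/(|A|+|B|)$ and a
  size-weighted overall value that equals the fraction of shared subjects
  kept together (and is therefore symmetric in its two arguments).

`run_pipeline()` strings the stages together over the
(2 atlases × 2 inclusion criteria) grid — the second criterion excludes
dual-diagnosis subjects — with every stage seeded from one master seed, so
a report reproduces bit-identically.

## Numerical choices and degenerate inputs

* Features are per-ROI z-scored after covariate adjustment and before
  fitting (margin methods are scale-sensitive); `standardize = FALSE`
  disables this.
* Covariate adjustment fits on the pooled sample by default;
  `method = "control_only"` estimates slopes on controls alone.
* Hyperparameters: `cost = 0.25`, `n_restarts = 20`,
  `max_iterations = 50`, `consensus_trim = 0.10`. The inner solver runs at
  most 200 sweeps to a projected-gradient tolerance of `1e-4`; assignment
  updates only need decision-value *ranks*, so looser inner tolerances do
  not change fitted labels in practice.
* Prediction ties break to the lowest subtype index; empty-subtype
  reseeding is deterministic (worst-explained subject); constant covariates
  are dropped with a warning; constant variables in two-sample tests return
  $t = 0, p = 1$ when group means agree.
* The tie rule in model selection prefers the smaller $k$ (parsimony).

## Desk-scale problem sizes

The test suite and the acceptance script exercise the pipeline at sizes
chosen to keep a full run on one CPU in minutes rather than days:
planted-recovery cohorts of 80 controls / 120 clinical / 100 ROIs with
`k_range = 2:4`, 10 folds and 8 restarts per CV fit; calibration cohorts of
40/60/30 with 5 folds and 99 permutations; pipeline-level checks at 50/70/60
with 49 permutations. These are the package's validation defaults, not
statements about the sizes a real analysis should use; a real cohort at 400
ROIs with `k_range = 2:10`, 10 folds, 20 restarts and 5000 permutations is
simply a larger configuration of the same calls.

## Known limitations

* Linear faces only; no kernels. Nonlinear deviation geometry is out of
  scope.
* The alternating optimization is a local method; the enumeration oracle in
  the test suite verifies it reaches within 5% of the exhaustive optimum on
  small instances, but no global guarantee exists at scale.
* The label-shuffling permutation scheme tests the null "no clinical/control
  structure anywhere", not "exactly k₀ clusters"; it cannot distinguish
  k = 2 from k = 3 under strong structure.
* Dice alignment and the aligned Hamming distance use exhaustive bijection
  search and are limited to k ≤ 8 (ample for this design).
* The cohort generator's independence assumptions (see above) make absolute
  runtimes and recovery rates optimistic relative to spatially correlated
  real data.
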