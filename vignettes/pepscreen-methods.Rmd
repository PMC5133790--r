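---
title: "Methods: sparse PLS-DA screening of a urinary peptidome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse PLS-DA screening of a urinary peptidome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

This vignette is the package's own account of the statistics it
implements: the models, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data results do and do not
say about real data.

## The data and the compilation model

A CE-MS urinary peptidome run reports, per detected peptide, a molecular
mass (0.8–30 kDa), a normalized CE migration time (minutes) and a
normalized signal intensity (ion counts) that serves as relative
abundance. Runs are compiled into one samples × master-peptides matrix
under the pairwise identity rule: two features are the same peptide when
their mass deviation is below ±50 ppm **and** their migration-time gap is
below 2 min. Both inequalities are strict, and the ppm denominator is the
master (seed) mass, so the predicate is fixed and auditable.

The identity rule does not by itself define a clustering. `pepscreen`
uses greedy reference-based clustering: features are ranked by descending
cross-run occurrence (how many runs contain a matching feature), then by
descending intensity; each unmatched feature seeds a master, and later
features join the nearest matching master (smallest ppm deviation, ties by
smaller time gap). A master accepts at most one feature per run — the most
intense wins and the displaced feature seeds a new master, so duplicated
within-run detections are never averaged away. Consensus mass and time are
intensity-weighted means over members. The procedure is deterministic
given the ranking, conserves total detected intensity, and on small
instances provably coincides with exhaustive single-linkage clustering
whenever true peptides are separated by more than twice the tolerances
(this is tested). When true peaks are closer than the tolerance — which
the matching rule cannot resolve even in principle — greedy and
single-linkage results may differ; real chimeric peaks are out of scope.

Run-level normalization against internal standards is a median-ratio
scaling: one factor per run, the median over matched standards of
(reference intensity / observed intensity). Data that are already
normalized upstream (including the synthetic generator's output) bypass
the step with identity factors. Migration-time normalization is assumed
already applied by the instrument software and is not re-estimated.

## Sparse PLS-DA

Let $X$ be the $n \times p$ abundance matrix (columns centered and scaled
to unit variance; zero-variance columns keep scale 1 and thereby earn
zero loadings) and $Y$ the column-centered one-hot indicator of the $K$
classes. Per component $h$, the X-loading $a_h$ is the dominant left
singular direction of $M_h = X_h^\top Y_h$, made sparse by
soft-thresholding

$$ a \leftarrow \operatorname{sign}(v)\,\max(|v| - \delta, 0), \qquad
   v = M_h q, $$

with $\delta$ the $(\texttt{keep\_x}+1)$-th largest $|v|$ — the smallest
threshold leaving at most `keep_x` nonzeros — followed by renormalization
to unit length; $a$ and the Y-direction $q$ are iterated to convergence
(tolerance $10^{-9}$, at most 500 iterations, initialized from the SVD of
$M_h$). Scores are $t_h = X_h a_h$, and both blocks are deflated by
regression on $t_h$, which makes scores mutually orthogonal. Sign
indeterminacy is fixed by making the largest-magnitude entry of each
loading column positive, so loadings are comparable across cross-validated
refits — a prerequisite for the ±0.15 consensus below. With
`keep_x = p` the algorithm is exactly dense PLS-DA; the tests verify this
against an independent eigendecomposition implementation to $10^{-6}$.

Classification assigns a projected sample to the class of the nearest
centroid (Euclidean distance in score space), with exact ties going to the
first class in training label order. Nearest-centroid is the simplest rule
consistent with how these models are used for screening; it is not tuned.

Two interpretation choices were genuinely open:

* **"Number of peptides in a model"** is read as `keep_x` applied
  identically to every component (the semantics of the reference
  implementation's `keepX`); the distinct-peptide count across components
  is also reported by `glance()`, since a two-component model with
  `keep_x = 15` may use up to 30 distinct peptides.
* **Log-transformation** of abundances before fitting is off by default
  (raw relative abundances enter the scaler); a `log1p` switch is
  provided. The screening conventions below are unaffected by the switch's
  default because the consensus operates on loading magnitudes either way.

## The model search

A basic model is a (grouping, week, components, peptides) tuple. The grid
crosses: the four arms per week (components 1–3), the merged N/HA/HL
scheme per week (components 1–2; the two standard-diet arms are
statistically indistinguishable, so merging them gains power), and the 16
treatment × week groups (components 1–15), each with 1–50 peptides per
component — 600 + 400 + 750 = 1,750 models.

Cross-validation partitions **rats**, never samples, into 10 stratified
folds, so a rat's repeated collections never straddle a split. The
parenthetical "excluding one sub-group per step" is read as the ten folds
of a single 10-fold pass, not 10 × 10 repeated CV; fold membership is
fixed by one seed-derived shuffle per (grouping, week) slice and shared
across the slice's models, so error differences across the grid reflect
model complexity, not fold luck (`shared_folds = FALSE` redraws per
model). A draw that strands an entire class outside some training fold is
redrawn with a new seed-derived shuffle, up to ten times, then fails
loudly. The five lowest-error models per week are kept for screening;
ties resolve toward parsimony (fewer peptides, then fewer components,
then enumeration order).

## Screening conventions

A peptide is a candidate biomarker when its absolute loading is at least
0.15 — on any component, by default; a per-component mode exists because
the rule's component scope is ambiguous — in **all five** screened models,
and it is detected in more than 30 % of the collected samples of at least
one group that week (strict `>`, matching the rule's "more than" reading;
at the study's group sizes of 5–12 samples the attainable frequencies step
by ~8–20 points, so `>` versus `≥` is unobservable there). Frequencies
use the actually-collected sample count as denominator, because real
collections go missing.

Group means average over **all** collected samples with non-detections
contributing zero. Whether published panels average detected samples only
cannot be decided from printed data; the choice is exposed but the
shipped fold-change anchors use printed means directly, so they are
unaffected.

Fold changes follow the signed-ratio convention reverse-engineered from
the published panel and verified on its rows: ratio of larger to smaller
group mean, negative when the case group is smaller, `1` for equal
positive means, and `na` whenever **either** mean is zero (every published
`na` row has a zero mean on one side). One published row (week-3 peptide
8116, HL) sits exactly on a 2-decimal rounding boundary
(392.6/104.0 = 3.775): the printed means cannot pin its second decimal,
and the package reports the conventionally rounded −3.78 against the
printed −3.77.

## The synthetic generator

The generator's job is to reproduce the statistical structure the
analysis assumes, with known truth — not to mimic spectra. Defaults
emulate the study design: 888 peptides, 6 rats in each of 4 arms, 4
weekly collections, 55 planted discriminant peptides.

* Baseline log-abundance per peptide: $\mu_j \sim \mathcal N(\log 500, 1)$,
  spanning the heavy right-skew seen in published mean abundances
  (roughly 10 to 5 × 10⁴ ion counts).
* Planted effects: HA shifts by ±1.5 natural-log units (≈ 4.5-fold, sign
  drawn once per peptide); HL sits at fraction λ of the N→HA shift, with
  λ = 0.5 in weeks 1–3 and 0.95 in week 4 — the "intermediate profile
  that vanishes at week 4" pattern.
* Observation: log-normal with SD 0.8 around the group log-mean, observed
  with a logistic detection probability in the centered log-mean (unit
  slope), calibrated by root-finding so the average detection probability
  is 0.6; otherwise the abundance is exactly 0. This zero-inflated
  log-normal is the simplest mechanism producing both exact zeros and
  skewed positives.
* Whole rat-week collections are dropped with probability 0.04, echoing
  the reduced group denominators visible in published frequency columns.
* True masses are laid out log-spaced over 0.8–30 kDa with stratified
  jitter, guaranteeing pairwise separation far beyond twice the matching
  tolerance; per-run features jitter by ≤ 20 ppm and ≤ 0.5 min.

Within-group correlation between peptides, migration-time drift, isotope
or charge artifacts, and week-varying effect sizes are deliberately not
modeled. The last omission matters for interpreting recovery numbers: in
real studies the weekly panels are nearly disjoint (a published 61-row
panel collapses to 55 unique peptides), because the biology drifts week
to week, whereas the generator's planted effects are constant across
weeks 1–3, so the weekly selections here overlap heavily and the
union-over-weeks sensitivity saturates near the size of a single weekly
panel. Passing tests therefore demonstrate that the machinery applies the
rules correctly and recovers the dominant planted signal — measured
end-to-end sensitivity with the default effect sizes is ~0.4 with at most
a handful of false selections per week — not that any fixed sensitivity
level would transfer to real CE-MS data.

## Numerical and reproducibility choices

* All stochastic stages consume explicit integer seeds; a pipeline
  configuration reruns bit-identically, and the resolved configuration is
  written as YAML beside the outputs.
* Fold assignment, feature ranking and model enumeration have
  deterministic total orders; residual ties (equal ppm deviation, equal
  error rates, equidistant centroids) all have documented tie-breaks.
* The NIPALS iteration measures convergence sign-insensitively, capping at
  500 iterations; in practice it converges in well under 50.
* Rendering follows the published precision: abundances and frequencies
  to 1 decimal, fold changes to 2, `na` for undefined folds; reports
  round-trip losslessly at that precision.
* Problem sizes in the test suite are chosen to keep the full suite
  around two minutes: unit fixtures use tens of peptides, the
  end-to-end acceptance checks run the full 888-peptide design with a
  peptide-count grid thinned to {5, 10, …, 50} and the weekly grouping
  schemes, and stochastic properties (chance-level CV error, the
  N–HL–HA component-1 ordering) average over 20 seeds.

## Known limitations

* The compiler's greedy clustering is order-dependent in the regime the
  identity rule itself cannot resolve (true peptides closer than the
  tolerances); its oracle guarantee holds only for separated peptides.
* Nearest-centroid classification ignores score covariance; a Mahalanobis
  or max-posterior rule could behave differently on strongly elliptical
  classes.
* Cross-validated error of the selected best models is an optimistic
  estimate of generalization (selection and estimation share the same
  CV); the search deliberately mirrors the screening procedure it
  implements rather than adding nested CV.
* Peptide sequence and protein identity are carried as optional
  annotations only; nothing is inferred from sequence.
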