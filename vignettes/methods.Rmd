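---
title: "Quantifying and classifying interneuron morphologies with morphotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying interneuron morphologies with morphotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotype)
```

## The problem

Cortical GABAergic interneurons are conventionally sorted into named
morphological types — chandelier (ChC), Martinotti (MC), bitufted (BTC),
double bouquet (DBC), and the nest, small and large basket cells (NBC,
SBC, LBC, jointly the compound basket class BA). Expert classification is
partly subjective; a supervised classifier trained on labeled
reconstructions makes the mapping from quantitative morphology to type
explicit, reports its own confidence, and can flag cells it consistently
fails to place — candidate atypical morphologies.

`morphotype` implements that pipeline end to end: SWC reconstruction
input, quality control and cohort exclusion rules, a catalog of 103
axonal and dendritic morphometrics, non-parametric feature selection,
class rebalancing, one-versus-all classification under repeated
stratified cross-validation, multi-class combination, and atypicality
reporting. A seeded synthetic-morphology generator stands in for real
reconstructions so that every stage is testable without downloads.

## Coordinate conventions and data model

A neuron is a forest of labeled points (soma, axon, dendrite) with parent
links, centered so that the soma centroid is the origin. Y is the radial
cortical axis with the pia in +Y, X is tangential, and Z is slice depth.
A *branch* runs from a root or branching point to the next branching
point or terminal tip; consecutive branches share their branching node.
Nodes with three or more children (multifurcations) terminate branches
exactly as bifurcations do but are excluded from all angle and
partition-asymmetry statistics, since angle measures at multifurcating
nodes are not well defined.

## The morphometric catalog

`feature_catalog()` fixes 103 named features: 55 standard metric and
topological measures and 48 custom quantifications of the Petilla
descriptors. Dendritic features carry a `d.` prefix, axonal
terminal-branch features a `t.` prefix.

Standard features are per-arbor summaries (avg, sd, med, max) of branch
path lengths, stem/bifurcation/terminal counts, centrifugal branch
order, arbor extent, distances to the soma, remote bifurcation/tilt/
torque angles, and partition asymmetry `|l - r| / (l + r - 2)` over
subtree tip counts. Measures known to depend on reconstruction
granularity — diameters, local (first-segment) bifurcation angles,
segment counts and lengths — are deliberately absent, because tracing
granularity differs across laboratories and even within one data set.

Three numerical choices harden the remaining features against
granularity:

* Distance averages and standard deviations are **exact line integrals**
  of the distance along each segment, length-weighted over the arbor
  cable. Collinear subdivision of segments therefore changes them by
  nothing beyond floating-point error (the test suite asserts < 1e-9),
  whereas per-node averages would drift with node spacing. Maxima are
  taken over nodes, where they are exact.
* Point-cloud features (orientation, grid occupancy, centroids) use a
  **1-micrometer arc-length resampling** of the cable with midpoint
  placement, so dense tracing does not over-weight a region.
* Remote (endpoint-based) angles are used instead of local ones. The
  remote tilt angle at a bifurcation B is the angle between the vector
  back to the parent-branch start and each child endpoint vector,
  averaged over the two children (a parent running straight into
  symmetric children at ±45 degrees yields 135 degrees per child);
  torque is the angle between the normals of consecutive bifurcation
  planes, folded to [0, 90] so plane orientation is immaterial.

Custom features quantify the Petilla descriptors in the X–Y projection:

* **Orientation and extent** — eccentricity `1 - lambda2 / lambda1` from
  the eigenvalues of the X–Y covariance of the resampled cloud (1 for a
  line, 0 for a circle), radial alignment `|cos|` of the principal axis
  with +Y, coordinate moments (`y_mean`, `y_std_mean = y_mean / y_sd`,
  `x_mean_abs`, spread ratios `ratio_x`/`ratio_y`, extremes).
* **Grid density** — a 20-micrometer square grid over the projection:
  occupied surface (`grid_area`), mean points per occupied cell
  (`grid_mean`, branch clustering), cable length per surface
  (`density`), and the mean pairwise distance among bifurcations
  (`density_bifs`; low values mean dense, local arborization).
* **Laminar distribution** — the soma's depth within its home layer is
  unknown and layer thicknesses vary, so laminar reach is a Monte-Carlo
  probability: each draw samples thicknesses from truncated normals and
  the soma offset uniformly within the home layer, then tests the
  arbor's Y-extent against the realized boundaries. `translaminar` is
  the probability of leaving the home layer, `l1_prob` that of reaching
  L1, and `l1_width`, `l1_bifs`, `l1_gxa` are unconditional expectations
  (zero when L1 is missed) of the arbor's width, bifurcation count and
  horizontal fan above the L1 boundary — the Martinotti "fan in L1"
  pattern. With 1000 draws the binomial standard error of a probability
  is at most 0.016; the estimate is seeded and therefore reproducible.
* **Dendritic polarity** — the PCA eccentricity of the unit insertion
  vectors from the soma to each dendritic root separates bipolar /
  bitufted (eccentricity near 1) from multipolar dendrites; the
  indicator `d.multipolar` uses a 0.85 cutoff, a deliberately strict
  value since truly bipolar insertions sit essentially on a line.
  `d.displaced` is the X–Y distance between the length-weighted
  dendritic and axonal centroids.
* **Pattern scores** — the chandelier "short vertical terminal" count
  (terminal branches with endpoint displacement at most 50 micrometers
  vertically and `|dY| >= |dX|`) and `axon_origin`, the Y component of
  the unit vector to the axonal root (+1 when the axon leaves the top of
  the soma, typical of Martinotti cells).

The exact membership of the custom set is pinned by `feature_catalog()`:
where a descriptor admits several equivalent summaries we fixed one
(e.g. signed `x_mean`, `y_max`/`y_min`, the per-process `density`), and
the catalog is asserted to contain exactly 55 standard and 48 custom
names.

## Quality control and cohort exclusions

`qc_report()` flags, deterministically: segments longer than 100
micrometers (tracing jumps; curated data have shown single 285-micrometer
segments against a 2-micrometer median), total axonal length below 3000
micrometers (too short to classify; the threshold sits above documented
2500 and 2850 micrometer exclusions), axonal arbors whose Z-range over
cable length falls below 1/100 (slice-flattened arbors; typical ratios
are near 1/60), axons with more than one root component (our operational
proxy for an "interrupted" arborization, which the original analyses
identified by eye), and multifurcation counts. `apply_exclusions()`
removes scarce types (BP, NGC by default) first and then cells flagged
with interrupted or short axons; long segments and flat arbors are
reported but retained, mirroring how such anomalies are handled in
curated sets.

## The synthetic-morphology generator

`generate_neuron()` grows an arbor by recursive binary branching:
straight branches traced in 2-micrometer steps (matching the median
segment length of fine reconstructions), lognormal branch lengths,
Gaussian remote bifurcation angles, and a per-type radial drift applied
to the parent direction before the children are rotated apart. Because
branches are straight and the drift acts before the split, the realized
endpoint angle at each bifurcation equals the Gaussian draw exactly —
the generator's contract is controllable summary statistics, not
biological realism. Dendrites are either multipolar (several stems in
random directions) or bipolar (exactly two stems on opposite Y sides).

The default templates encode only the qualitative contrasts that the
classifier must recover: MC axons ascend with wide angles and bitufted
dendrites; baskets are local with sharp remote angles and many dendritic
stems (LBC longer-branched, SBC short and dense); DBC is radially
descending, narrow and bipolar; ChC forces short vertical terminal
branches; BTC is bipolar with mild ascent. Template means were chosen
once so that expected axonal length clears the short-axon threshold with
margin and the MC templates reach L1 with moderate probability.

What the generator does *not* emulate: tortuous branches (tortuosity is
exactly 1 by default), boutons and spines, realistic per-type
morphometric distributions, soma geometry (a single point), or
inter-laboratory granularity differences. Passing pipeline tests on
synthetic cohorts therefore demonstrates parameter recovery under known
separable conditions — not real-data accuracy, which requires real
reconstructions and their metadata.

`inject_defects()` produces copies guaranteed to trigger each QC flag
(detached subtree, axon rescaled to 2500 micrometers, one segment
stretched to 285 micrometers, Z compressed by 0.05), which is how the
cohort-exclusion arithmetic is exercised: a 228-cell fixture — 222 cells
of the seven classified types with 3 interrupted and 2 short axons, plus
3 BP and 3 NGC cells — reduces to exactly 217.

## Feature selection and rebalancing

`kw_select()` ranks features by the two-group Kruskal–Wallis rank test
(tie-corrected) with Benjamini–Hochberg FDR control at alpha 0.05;
constant features receive p = 1 by convention. `rf_bvi()` is the
balanced random-forest variable importance: the arithmetic mean of the
per-class permutation importances (mean decrease in class-wise
out-of-bag accuracy), selected above 0.01, so the scarce positive class
counts as much as the majority; the standalone default of 20000 trees
gives stable rankings, while in-fold use reduces the forest (2000 trees
by default) to keep repeated cross-validation affordable.
`correlation_prune()` greedily removes features correlated above 0.9
with a better-ranked one.

`hybrid_sample()` rebalances one-versus-all training sets by keeping a
uniform random half of the negatives and adding two SMOTE positives per
real positive (each synthetic point interpolated toward one of the k = 5
nearest positive neighbors). On a 7-positive / 210-negative task this
retains 105 negatives and adds 14 synthetic positives — a 126-row
training set. When the positive class is already the majority (the BA
setting) nothing is removed or added. Both rates are configurable; the
defaults are the package's fixed operating point, not tuned values.

## Classification and evaluation

Nine classifiers run with fixed parameters (no tuning): CART (min split
10, min leaf 5), kNN (k = 5, Euclidean), LDA, Gaussian naive Bayes,
random forest (2000 trees, mtry = sqrt(p)), lasso logistic regression
(lambda = 0.01, standardized), RBF SVM (gamma = 1/p, C = 1, Platt-scaled
probabilities with a training-set sigmoid fallback when the internal
calibration is unavailable), a single-hidden-layer neural network (5
units), and 3000 depth-1 gradient-boosted trees with shrinkage 0.001.
Distance- and gradient-based learners see train-fold-standardized
inputs; tree, Bayes and LDA models see raw values. Missing values are
imputed with train-fold medians.

`cross_validate()` runs stratified k-fold cross-validation (k = 10 by
default; use k = 7 when only seven positives exist) with feature
selection and sampling executed **inside** the loop on training folds
only — selecting features on the full data before cross-validating
leaks held-out information and inflates apparent accuracy, which the
test suite demonstrates with a deliberately leaky reference. Because
sampling is stochastic, cross-validation repeats ten times when sampling
is enabled; per-repetition fold-pooled confusion counts yield an
F-measure `2PR / (P + R)` (defined as 0 when TP = 0), and counts are
averaged across repetitions, which is why reported counts may be
fractional. One master seed fans out to folds, sampling, Monte-Carlo
features and stochastic learners, making every result reproducible.

`combine_multiclass()` assigns a cell to the base type whose
one-versus-all model is most confident, breaking exact ties
alphabetically. `atypicality_report()` aggregates per-cell predictions
over repetitions and models: labeled positives that are almost never
predicted positive across models are the candidate atypical
morphologies.

## Problem sizes and verification

The package's own verification runs at desk scale, chosen once: property
tests use toy geometries and random trees of up to 30 nodes against
first-principles oracles; laminar Monte-Carlo checks use 2000 draws
against closed-form uniform-offset geometry; the parameter-recovery
suite generates 50 cells per type (350 cells), extracts features with
200 Monte-Carlo draws, and runs the KW + sampling + random-forest
pipeline under 10x10-fold cross-validation in every one-versus-all
setting, requiring a mean F-measure of at least 0.9 per type. On the
default templates all types reach F close to 1 — the synthetic contrasts
are deliberately separable; this validates the machinery, not the
difficulty of real data.

## Known limitations

* Synthetic cohorts are far more separable than real reconstructions;
  absolute F-measures on them say nothing about real-data performance.
* The laminar thickness table is a configuration input; the shipped
  default is a synthetic rat-somatosensory-like profile.
* The interrupted-axon flag is a structural proxy (multiple axonal root
  components) for what is ultimately a curator's judgment.
* kNN class probabilities are neighbor-vote fractions and therefore
  coarse (multiples of 1/k); SVM probabilities depend on the calibration
  sample.
* Bouton- and spine-based descriptors are out of scope: they are absent
  from SWC reconstructions.
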