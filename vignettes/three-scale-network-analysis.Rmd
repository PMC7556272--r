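---
title: "Three-scale analysis of brain functional networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-scale analysis of brain functional networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices behind
TriScaleNet. It is the package's methodological record: anything stated here
is either a definition or a decision, not an empirical claim — empirical
behaviour is established by the test suite and `scripts/acceptance.R`.

# From time series to weighted networks

For regional time series $X_i$ and $X_j$, functional connectivity is the
absolute Pearson correlation $w_{ij} = |r(X_i, X_j)|$, assembled into a
symmetric $N \times N$ matrix with a zero diagonal (`computeFC()`). Taking
the modulus treats anti-correlation as coupling of equal strength; no
Fisher transform or signed-network variant is offered. A zero-variance
region is degenerate rather than fatal: its connectivity is set to zero
with a warning, so a flat-lined channel cannot silently poison a cohort
run. Group-level networks are the element-wise mean of the individual
matrices (`groupMeanNetwork()`), averaging before thresholding.

Thresholding (`thresholdBySparsity()`) keeps the $K = \mathrm{round}(s
\cdot N(N-1)/2)$ strongest edges at sparsity $s$, with their weights — the
networks stay weighted throughout. Two conventions are fixed purely for
reproducibility, since neither affects the science but both affect
bit-level determinism:

* $K$ uses half-to-even rounding (R's `round()`);
* ties at the cut-off are broken by ascending $(i, j)$ lexicographic order,
  which also makes edge sets nest monotonically across the sparsity grid.

All sweeps use the grid $\{0.05, 0.06, \ldots, 0.50\}$ (`sparsityGrid()`,
46 values). At the low end, thresholded networks may contain isolated
regions; `isolatedFraction()` surfaces this.

# Scale I: global metrics

Shortest-path computations need a weight-to-length map; TriScaleNet uses
$\ell_{ij} = 1/w_{ij}$, the dominant convention for correlation-weighted
brain networks (stronger coupling = shorter distance).

* **Clustering** `clusteringCoefficient()`: Onnela's weighted form,
  $C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij} \hat w_{ih} \hat
  w_{jh})^{1/3}$ with weights normalised by the network maximum, so $C \in
  [0, 1]$. Nodes of degree $< 2$ contribute 0. This variant is computed
  directly (igraph offers only the Barrat form).
* **Path length** `characteristicPathLength()`: mean Dijkstra distance over
  ordered *reachable* pairs, with the unreachable-pair fraction reported
  alongside. Excluding unreachable pairs (rather than propagating
  $\infty$) is forced by the low-sparsity regime where isolated regions
  exist; the price is that $L$ is *not* monotone in sparsity until the
  network is connected — newly reachable, distant pairs can raise the
  reachable-pair mean. The tests therefore check monotonicity only on the
  connected regime, and efficiency (which has no such caveat) on the whole
  grid.
* **Efficiency** `globalEfficiency()`: mean inverse distance with
  $1/\infty = 0$.
* **Small-worldness** `smallWorldness()`: $SW = (C/\langle C_{rand}\rangle)
  / (L/\langle L_{rand}\rangle)$ against degree-preserving Maslov–Sneppen
  rewired nulls (`rewirePreservingDegree()`, 10 attempted swaps per edge;
  edge weights travel with swapped edges so the weight multiset is
  preserved). The null count defaults to 1,000 in the full analysis profile
  and is scaled down (25–100) in demonstrations and tests; nulls get seeds
  `seed + 1 .. seed + n`. Rewiring rather than an analytic lattice/random
  reference was chosen because it conditions on the exact degree sequence
  and weight set, the most conservative standard null.

# Scale II: betweenness hubs

`nodeBetweenness()` computes weighted shortest-path betweenness (Brandes,
unordered pairs, endpoints excluded, fractional accumulation over
equal-length paths). Since hubs are defined on *mean-normalised* values
$BC_i = bc_i / \langle bc \rangle$ (`normalizeBC()`), any constant-factor
pair-counting convention cancels. Hubs are $BC_i > 2.5$ (strict
inequality); 1.5 and 2 are supported as laxer alternates and can only
enlarge the hub set. `hubStability()` tabulates hub flags over the grid for
"stable hub" summaries; it operates on group-level networks only, while
per-subject betweenness feeds the statistics and the classifier — the two
paths are tagged (`level` attribute) and never mix.

A caveat discovered during validation and worth recording: in *any* single
weighted noise network, nested thresholds keep the incidentally strongest
node persistently central, so even a structureless network shows some
high-$BC$ node across many sparsities. The meaningful null statement about
hubs is therefore reproducibility — across replicate null cohorts, no
specific region is flagged consistently — and that is what the tests
assert.

# Scale III: modular structure

`modularityQ()` is weighted Newman modularity at resolution 1;
`detectModules()` maximises it with seeded multi-restart Louvain (default
20 restarts, best $Q$ kept, labels canonicalised so module 1 contains the
lowest region index — making crosswalk tables reproducible).
`permutationTestQ()` compares the observed $Q$ with nulls in which the
network is randomised (degree-preserving rewiring by default; weight
shuffling on the fixed topology as an alternative) and communities are
re-detected per null with the *same* restart budget as the observed
network — equal treatment is what keeps the null p-value uniform. The
p-value uses the add-one permutation formula $p = (1 + \#\{Q_{null} \ge
Q_{obs}\})/(1 + n_{perm})$, so $p$ can never be 0 and `nPerm < 19` warns
that the attainable floor exceeds 0.05. `moduleCrosswalk()` tabulates how a
reference partition's modules redistribute in an alternate partition.

# Group statistics

Demographics follow a normality gate: Lilliefors test at $\alpha = 0.05$
per group (`normalityGate()`), routing to Welch's t-test when both groups
pass and the Wilcoxon rank-sum test otherwise; gender uses Fisher's exact
test, implemented by direct hypergeometric enumeration
(`fisherExact2x2()`, two-sided as the sum of table probabilities no larger
than the observed one, with a $1 + 10^{-7}$ relative guard against
floating-point ties; a zero margin returns $p = 1$).

Metric group differences use logistic regression of group on the metric
with gender (coded 0/1) as the only covariate — age is deliberately not
adjusted — reporting the Wald p-value of the metric coefficient. Perfect
separation is flagged and the p-value withheld rather than reported as a
misleading near-zero. Nodal tests carry both the unadjusted $p<0.05$ flag
and the Bonferroni flag at $0.05/116$ (the nodal family size); global
metrics are not multiplicity-corrected across sparsities. Note that Wald
tests on strongly zero-inflated nodal betweenness at small $n$ are
conservative; the calibration tests therefore bound the corrected
family-wise error and check nominal two-sided calibration on a
well-behaved global metric. Associations with cognitive scores use partial
correlation controlling gender (residual-on-residual Pearson, $t$ reference
with $n - 3$ df).

# The two-layer random-forest classifier

The feature table at one sparsity has 124 columns in fixed order: ADAS13,
CDRSB, MMSE, FAQ, $C$, $L$, $GE$, $SW$, then per-region betweenness
`bc_1..bc_116` from the *individual* networks. Layer 1 ranks all features
by random-forest importance — permutation-based out-of-bag accuracy loss by
default, since that matches the "importance via OOB error" idea;
impurity-based ranking is available by flag. Layer 2 trains on the top $N$
(swept over 5–30) under stratified 10-fold-outer / 5-fold-inner nested CV,
tuning trees $\in \{100, 200, 500\}$ × depth $\in \{2, 3, 5, \text{unbounded}\}$
(the grids are unprescribed upstream; these are small, overridable
defaults). Accuracy, sensitivity and specificity are pooled over outer
folds; AUC is rank-based on the pooled out-of-fold probabilities.

One design decision deserves emphasis: ranking the 124 features *once on
all rows* before cross-validation leaks test information into feature
selection and biases accuracy upward. The default here re-ranks within
each outer training set (unbiased); `globalRanking = TRUE` reproduces the
global-ranking variant for comparison. The leakage property is testable —
flipping an outer-test label must not change that fold's selected
features — and is asserted in the suite. Stratified folds are used because
at $n \approx 60$ unstratified folds can lose a class entirely, making
sensitivity/specificity undefined.

# The synthetic cohort generator

The generator (`cohortSpec()`, `generateCohort()`) defines the study
conditions under which everything above is exercised.

**Signal model.** Each subject's $T \times N$ series is drawn i.i.d. over
time from a zero-mean Gaussian whose correlation matrix has $\rho_{in}$
within planted modules, $\rho_{out}$ between them, and an added `hubBoost`
on the cross-module rows of hub regions. Pearson correlation is the only
statistic consumed downstream, so temporal structure is irrelevant to first
order; an AR(1) knob (`arCoef`) exists for robustness checks but defaults
to white noise. Hub boosts can break positive semi-definiteness; repair is
by eigenvalue clipping at zero followed by unit-diagonal rescaling —
deterministic and standard — and sampling uses the symmetric eigenvalue
square root, which tolerates the singular repaired matrix.

**Defaults** (chosen once as a realistic emulation of a 116-region
parcellation, and fixed): 30 subjects per group, $T = 135$, four equal
planted modules, $\rho_{in} = 0.4$, $\rho_{out} = 0.1$, one hub per module
(`hubBoost` = 0.3). The case group receives additive deltas: $\rho_{out}$
+0.08, `hubBoost` −0.1, and a split of planted module 1 into two (its
second half relabelled), emulating community reorganisation. The balance
matters: weakening hubs *lengthens* paths (hubs are the network's
shortcuts), while raising between-module correlation shortens them;
calibrating the two so the between-module term dominates reproduces the
intended clinical direction — shorter characteristic path length and
higher global efficiency in the case group — at every tested sparsity,
while still weakening hub centrality. Cognitive scores are
`intercept + coef · property + caseShift · I(case) + noise`, with the case
group impaired (higher ADAS13/CDRSB/FAQ, lower MMSE); per-score means and
SDs use clinically plausible magnitudes, and scores can alternatively be
driven by a subject-level network property ($C$, $L$ or $GE$ at sparsity
0.16) for parameter-recovery tests. Male probability differs by group
(0.56 vs 0.39), giving the gender covariate something to do.

**Ground truth** records per-group partitions, per-group hub sets and the
feature-table columns that carry group signal by construction (the four
scores, the four global metrics when topology differs, and the betweenness
columns of boosted hubs) — enabling recovery tests with known answers.

**What it does not emulate.** Haemodynamic autocorrelation and filtering
(unless `arCoef` is set), spatial adjacency of regions, heavy-tailed or
floor/ceiling-limited score distributions (CDRSB and FAQ are nonnegative
and discrete in reality; the Gaussian model can produce small negative
values), site/scanner effects, age structure, and any preprocessing
artefact. Passing tests therefore demonstrate correctness of the
*computations* and sensible behaviour under a controlled signal model —
not that real cohorts will show effects of this size.

# Determinism and problem sizes

Every stochastic step takes an explicit seed; `runFull()` derives stage
seeds from one master seed by fixed offsets, so a configuration reproduces
bit-identically. The test and demonstration profiles scale simulations to
what a laptop runs in minutes — small-world nulls of 25–100 instead of
1,000, 200 permutations instead of 1,000, calibration loops on 20–32-region
cohorts, the classifier's inner grid reduced where only a contract (not
peak accuracy) is under test — sizes chosen so each check retains its
statistical meaning. The full-scale profile is a configuration change, not
a code change.

# Known limitations

* Group-level thresholding after averaging is the only supported order;
  per-subject thresholds followed by mask conjunction are not offered.
* The permutation null for modularity re-detects communities per null,
  which is conservative; a faster fixed-partition variant is deliberately
  not provided because it inflates significance.
* Betweenness hubs in single weighted noise networks are not self-averaging
  (see Scale II); hub conclusions should always be read across replicates
  or sparsities, never from one network alone.
* Wald logistic inference at small $n$ on skewed nodal metrics is
  conservative; exact or permutation inference would be needed for
  power-critical nodal claims.
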