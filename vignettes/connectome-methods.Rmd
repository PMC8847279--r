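---
title: "Rich-club and small-world analysis of weighted structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club and small-world analysis of weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richnet)
```

# The problem

Diffusion-MRI tractography yields, for each subject, a symmetric
region-by-region matrix of white-matter connection weights — here
FA-based interregional connection weights in (0, 1], on a 90-region
cortical/subcortical parcellation. `richnet` implements the full
graph-theoretical comparison of two such cohorts (patients vs controls,
for example children after cleft-palate articulation rehabilitation vs
typically developing controls): small-world metrics, rich-club
organization, edge-class statistics, covariate-adjusted univariate group
tests, behavior correlation, and multivariate pattern analysis with a
linear SVM. Because raw clinical cohorts of this kind are rarely shared,
the package also ships a synthetic-cohort generator with planted ground
truth, so every stage can be exercised and scored end to end.

# Models and procedures

## Proportional thresholding

Comparing graph metrics across subjects requires equal edge counts, so
each matrix is thresholded to a fixed connection *density*: the
`k = floor(density * n(n-1)/2)` strongest edges are retained with their
weights. Metrics are swept over a density grid (default 0.05–0.50) and
summarized by the trapezoidal area under the metric-vs-density curve
(AUC), which avoids privileging any single threshold. Ties at the cut
are broken by lexicographic node-pair order; this makes thresholding
deterministic and the retained edge sets nested across densities.

## Small-world metrics

The network clustering coefficient Cp is the mean of the Onnela
weighted clustering coefficient,
$C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$
with weights normalized by the network maximum; nodes of degree < 2
contribute 0. The characteristic path length Lp is the mean Dijkstra
shortest-path length with edge distance 1/w over connected pairs;
disconnected pairs are excluded (and counted) rather than imputed,
which keeps Lp finite at sparse densities. Both are normalized by the
means of an ensemble of degree-preserving random networks:
$\gamma = C_p / C_p^{rand}$, $\lambda = L_p / L_p^{rand}$, and
small-worldness $\sigma = \gamma / \lambda$, with $\sigma > 1$
indicating small-world organization.

The weighted clustering formula is not uniquely fixed by common
toolboxes; we use the Onnela variant, the default family in standard
connectome software. Distances 1/w and exclusion of disconnected pairs
are likewise the standard connectome conventions.

## Null models

Reference networks are built by Maslov–Sneppen double-edge swaps
(igraph's `keeping_degseq`, 10 swap attempts per edge), which preserve
every node's degree exactly, followed by a random permutation of the
original weight multiset onto the rewired topology — total weight is
conserved, and the weight–topology association is destroyed. How (or
whether) weights should be preserved in the null is genuinely open in
the literature; the permutation choice is recorded in the ensemble
metadata (`weight_null = "permuted"`). Per-replicate seeds are derived
from one master seed by a counter scheme, so ensembles are reproducible
independently of execution order.

## Rich-club organization

The rich-club coefficient at degree k is
$\Phi(k) = 2E_{>k} / (N_{>k}(N_{>k}-1))$, the density of the subgraph of
nodes with degree above k, computed on binarized topology ("ratio of
existing to possible connections" is the binary definition; a weighted
variant is deliberately not used). $\Phi_{norm}(k) = \Phi / \Phi_{rand}$
normalizes by the rewired ensemble; values above 1 across a degree range
indicate rich-club organization. The analysis density defaults to 16%.

Rich-club *regions* are the top 15% of nodes (13 of 90) by nodal degree
averaged over all subjects, both groups pooled, so the selection cannot
favor either group. Ties at the cut break by higher average strength,
then lower node id. Edges then classify exhaustively into rich-club
(both ends rich), feeder (one end), and local (neither); per-subject
connectivity strength per class is the sum of retained edge weights, and
the three strengths partition the total retained weight exactly.

## Group statistics

"Corrected for age and sex" is implemented as residualization: values
are regressed on intercept + age + sex over all subjects pooled, and an
equal-variance two-sample t-test compares residuals between groups
(ANCOVA-style adjustment is the other defensible reading; the choice is
recorded in the output metadata, and with constant covariates both
reduce to the plain t-test). Edge-wise tests run on connections retained
in every subject at the analysis density, with per-edge significance at
p < 0.001 uncorrected by default — mirroring common practice in this
literature — and an optional Benjamini–Hochberg flag for stricter
control. The sex table uses the Pearson chi-square without continuity
correction. Behavior correlations are Pearson, patients only, because
the speech-intelligibility score is measured in patients.

## MVPA

Per connection class, features are the class's edges common to all
subjects, valued by edge weight. Classification is a linear SVM (libsvm
via e1071, the same library family the original analysis toolchain
wraps) under leave-one-out cross-validation. Inside each fold — never on
the held-out subject — features are ranked by the F-score
$F = [(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2]/(s_+^2 + s_-^2)$,
the top n are kept, training mean/sd standardize both partitions, and
the cost C is chosen by inner stratified 5-fold search over
{0.01, 0.1, 1, 10, 100}. Performance is accuracy, sensitivity (patients
positive), specificity, and ROC-AUC computed as the Mann–Whitney rank
statistic on decision values. The permutation test repeats the entire
pipeline on B label permutations and reports
$p = (1 + \#\{acc_{perm} \ge acc_{obs}\})/(B+1)$, which is never 0 and
bounded below by 1/(B+1).

Consensus features are those selected in *every* fold — a definition
that presupposes per-fold selection, which is why selection lives inside
the folds. Each consensus feature carries the sign of its mean SVM
weight; a region's weight is the sum of |mean weight| over incident
consensus features (one of several defensible aggregations; ours is the
simplest additive one), and weighted regions are nodes at least one
standard deviation above the mean region weight, with min–max
normalized weights for reporting. When all region weights are equal the
threshold degenerates to "all", and the report flags it.
`feature_count_search()` evaluates candidate feature counts by LOOCV
accuracy with ties to the smaller count, since no selection rule for
the count is fixed a priori.

# The synthetic cohort generator

`generate_cohort()` draws one template topology per cohort — a
stochastic block structure over a planted core of 15% of nodes
(core–core edge probability 0.90, core–periphery 0.62,
periphery–periphery 0.50) — and per-edge baseline weights from
Beta(5, 6) (mean ≈ 0.45, an FA-plausible distribution), boosted by
+0.18 on core–core and +0.08 on feeder edges so the planted core is
genuinely the high-degree rich club after proportional thresholding.
The block probabilities put whole-matrix density near 0.54, so the full
0.05–0.50 threshold sweep is supported, as it must be for matrices
analyzed over that range. Subjects share the template (as with
template-based connectome construction) and differ by Gaussian weight
noise (sd 0.05).

Planted signal: designated feeder and local edges receive a
standardized patient–control effect (default d = 1.5, 10 feeder + 10
local positive and 1 local negative, mirroring a predominantly
increased-in-patients pattern with a single decreased peripheral
connection); designated local edges couple linearly to the behavior
score at target Pearson r (defaults 0.45, 0.45, −0.44, matching the
magnitude of reported score–connection correlations). Planted edges are
assigned strong baselines (uniform 0.72–0.77, several noise sd above
the 16% cut; the negative-effect edge gets its shift magnitude added
back) so they survive thresholding in every subject and are therefore
testable — weak planted edges would silently drop out of the common
edge set rather than be missed statistically, which is a different
phenomenon from the one being tested.

Covariates: age ~ Uniform(6, 16) years, 21 males / 7 females per group
(so the demographic chi-square is exactly 0), optional confounding
slopes default 0. Behavior scores are Normal(91.6, 4.0) clamped to
[86, 100] — the rehabilitation-threshold floor and full score; clamping
raises the realized mean slightly above 91.6 and shrinks the sd, which
the score tests account for.

What the generator does *not* emulate: spatial embedding and
distance-dependent connectivity, hemispheric symmetry, realistic
degree-weight coupling beyond the block boosts, inter-subject
topological variability (the template is shared), and registration or
tractography error. Passing recovery tests therefore demonstrates the
*pipeline's* correctness on data satisfying its assumptions, not
performance on real tractography data.

# Numerical choices and degenerate inputs

- Matrix validation symmetrizes by averaging below asymmetry 1e-8 and
  errors above; diagonals must be exactly zero.
- $\Phi(k)$ is NA when fewer than two nodes exceed k; $\Phi_{norm}$ is
  NA where $\Phi_{rand} = 0$.
- Metric failures on a density grid (for example no connected pairs)
  are recorded as missing and excluded from the AUC with a warning;
  single-point grids get AUC 0 with a warning.
- Zero-denominator F-scores are flagged and ranked last; zero-sd
  features standardize with unit scale.
- The adjusted t-test errors on constant values; constant covariates
  are dropped.

# Problem sizes

Defaults are desk-scale, chosen so a full run takes minutes on one CPU:
null ensembles of 100 networks (small-world and rich-club), 100 label
permutations, and for the acceptance/driver scripts a step-0.05 density
grid with a 20-network ensemble per density for the per-subject sigma
curves and B = 49 permutations per class. Literature-scale settings —
5,000 small-world nulls, 1,000 rich-club nulls, 1,000 permutations,
step 0.01 — are one flag away (`analysis_config(full_scale = TRUE)`)
and change precision, not code paths. Calibration suites in the tests
use reduced cohorts (30 nodes, 5–20 subjects per group) for the same
reason.

# Known limitations

- The behavior coupling is induced against the *latent* score before
  clamping at the 86-point floor, so realized correlations are mildly
  attenuated (well inside ±0.1 of target on average).
- Residualization-then-t differs slightly from ANCOVA when covariates
  correlate with group; both are defensible readings of
  "corrected for age and sex".
- LOOCV accuracy on permuted labels can fall visibly below 0.5
  (anti-learning), a well-known LOOCV artifact; the permutation test
  accounts for it by re-running the full pipeline under permutation.
- Phi-against-null comparisons at degrees where the club has fewer than
  ~5 members are noise-dominated; summaries restrict to populated club
  sizes.
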