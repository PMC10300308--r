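---
title: "Individual metabolic brain networks by Jensen-Shannon divergence similarity"
author: "jsseNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual metabolic brain networks by Jensen-Shannon divergence similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsseNet)
```

## The problem and the model

Positron-emission tomography with fluorodeoxyglucose (FDG-PET) measures
regional glucose metabolism, but a single uptake value per region ignores
how regions co-vary. Group-level metabolic covariance networks recover that
structure only across subjects, sacrificing the individual. `jsseNet`
implements an *individual-level* metabolic connectome: for one subject, the
voxel intensities inside each atlas region are treated as draws from a
region-specific probability density, and the connection between regions $i$
and $j$ is the similarity of those densities.

Densities are estimated by Gaussian kernel density estimation (KDE) on a
single per-subject evaluation grid. Dissimilarity is measured in nats by
the Jensen-Shannon (JS) divergence

$$D_{JS}(P\|Q) = \tfrac12 D_{KL}(P\|M) + \tfrac12 D_{KL}(Q\|M),
\qquad M = \tfrac12 (P + Q),$$

where $D_{KL}(P\|Q) = \int P(x)\,\ln\frac{P(x)}{Q(x)}\,dx$ is the
Kullback-Leibler divergence. Unlike KL, JS is symmetric and bounded in
$[0,\ln 2]$, so the edge weight

$$W_{ij} = \exp\!\left(-D_{JS}(P_i\|P_j)\right) \in [0.5,\, 1]$$

is symmetric, never negative, and equals 1 exactly when the two regional
densities coincide. The $90 \times 90$ matrix $W$ over the cerebral AAL
regions (45 per hemisphere, cerebellum excluded) is the subject's metabolic
network.

Downstream, the weighted network is binarised at a grid of sparsity
thresholds, a panel of global and nodal graph metrics is computed at each
threshold and aggregated as the trapezoidal area under the
metric-versus-sparsity curve (AUC), groups are compared edge-by-edge and
metric-by-metric with two-sample t-tests, hubs are read off the group-mean
degree and betweenness maps, and a multi-kernel support-vector machine
(MK-SVM) fuses connection, global-metric and nodal-metric feature blocks to
classify cases against controls.

## Numerical choices in the divergence core

Several details are deliberate and tested:

* **Logarithm base.** Natural log. This makes divergences nats, the JS
  upper bound $\ln 2$, and the weight floor $e^{-\ln 2} = 0.5$.
* **Shared grid.** KL and JS require a common support, so all of a
  subject's densities are evaluated on one uniform grid (default $G = 256$
  points) spanning the subject's pooled intensity range padded by three
  times the largest per-region bandwidth. Masses are renormalised to sum
  to one, and divergences are computed as finite sums over the grid.
  A per-subject grid (rather than per-pair) caches $N$ densities and makes
  network assembly $O(N^2 G)$.
* **Bandwidth.** Silverman's rule per region by default (Scott's rule is
  available). Zero-spread samples degrade to a point mass at the nearest
  grid point, with a warning.
* **Zero handling.** The convention $0 \ln 0 = 0$ is applied term-wise. JS
  never needs epsilon flooring because $M \ge P/2$ wherever $P > 0$; raw KL
  returns `Inf` when `P` has mass where `Q` has none.
* **Clipping.** Floating-point noise is clipped at the analytic bounds
  $[0, \ln 2]$, so `ConnectivityMatrix` invariants hold exactly.

A useful consequence, covered by a test: global proportional intensity
normalisation (dividing a subject by their pooled mean) leaves $W$
unchanged, because Silverman bandwidths scale covariantly with the data.
Normalisation is still applied by default before network construction, as
is conventional for uptake images, and it does matter for the SUV feature
blocks.

## Graph metric panel

Networks are binarised by retaining the $k = \lfloor s\,N(N-1)/2 \rfloor$
strongest edges at each sparsity $s$ in an inclusive grid, by default
$0.02$ to $0.5$ in steps of $0.01$ — exactly 49 thresholds. Ties at the
cut are broken by lexicographic node-pair order so thresholding is
deterministic.

The global panel has 11 entries: assortativity $A_r$, modularity $Q$,
hierarchy $H_r$, global efficiency $E_{global}$, local efficiency
$E_{local}$, clustering coefficient $C_p$, normalised clustering $\gamma$,
normalised path length $\lambda$, small-worldness $\sigma = \gamma/\lambda$,
characteristic path length $L_p$, and synchronization $S_r$. Nodal metrics
are degree, betweenness, nodal clustering, nodal shortest path length and
nodal efficiency. Design decisions where the standard pipeline leaves
room:

* **Disconnected graphs.** At low sparsity the graph may fragment.
  Path-based quantities are computed over reachable pairs only and a
  per-threshold connectedness flag is recorded; efficiency-type metrics
  count unreachable pairs as zero contribution, which is their usual
  definition.
* **Modularity.** Greedy agglomerative Newman optimisation (igraph's
  fast-greedy), which is deterministic; a seeded Louvain would also do, but
  determinism simplifies testing and reproducibility.
* **Hierarchy.** $C \propto k^{-\beta}$ is fitted by regressing
  $\ln C_i$ on $\ln k_i$ over nodes with $C_i > 0$ and $k_i > 1$ (the
  logs are undefined otherwise) and reporting $\beta$ as minus the slope,
  the convention of the standard toolboxes. With fewer than two usable
  nodes the value is `NA` and the feature is dropped from selection; if a
  metric is undefined only for a held-out subject, its z-score is imputed
  at the training mean (zero) so one undefined feature cannot poison a
  kernel row.
* **Synchronization.** $S_r = \lambda_2 / \lambda_{max}$ of the graph
  Laplacian, a spectral measure of how easily the network settles into a
  common state.
* **Null models.** $\gamma$, $\lambda$, $\sigma$ are normalised against
  degree-preserving double-edge-swap rewirings (default 100 nulls per
  threshold, 10 attempts per edge, seeded). Tests verify the degree
  sequence is conserved exactly, that rewiring destroys clustering in
  clique-rich graphs, and that $\gamma, \lambda \approx 1$ when the input
  is itself a rewired random graph.
* **Betweenness.** Unnormalised counts with each unordered pair counted
  once; hub ranking is invariant to the normalisation constant.

Every per-threshold curve is summarised by its trapezoidal AUC over the
sparsity grid; those AUCs are the classifier features (11 global + $5N$
nodal per subject).

## Group statistics

Group comparisons use the pooled-variance Student t-test, two-sided, with
uncorrected p values by default (a Benjamini-Hochberg column is optional).
Hubs are nodes whose group-mean degree or betweenness exceeds the
across-node mean plus one sample standard deviation; the rule is invariant
under affine rescaling. Edgewise tests run over all $N(N-1)/2$
upper-triangle edges with the effect direction (increase/decrease in
cases) recorded for connectogram export.

## Classification

Five feature blocks per subject — connection weights, global-metric AUCs,
nodal-metric AUCs, and the SUVmean / SUVmax uptake baselines — feed nine
models: each baseline, each single block (C, G, N), and the kernel
combinations C+G, C+N, G+N, C+G+N. Each block gets a linear kernel on
z-scored, t-test-selected ($p < 0.05$) features; the multi-kernel machine
uses $K = \sum_m \beta_m K_m$ with $\beta$ on the simplex.

The evaluation is a stratified nested cross-validation: an outer K-fold
(default 10) for performance, and an inner K-fold (default 5) on each
outer-training set that picks $\beta$ (simplex grid, default step 0.1 — 66
candidates for three kernels) and the SVM cost $C$ (default
$2^{-5}..2^{5}$) by pooled inner-validation AUC, with ties resolved toward
a larger connection weight. Feature masks, standardisation statistics and
hyperparameters are fitted on training subjects only; the corner case
$\beta = e_m$ reproduces the single-kernel model exactly (tested). Out-of-
fold decision values are pooled into one ROC; accuracy, sensitivity and
specificity are read at decision threshold 0, and AUC is the tie-aware
rank statistic. Models are compared with the DeLong placement-value test
for correlated ROC curves, implemented in the package and cross-checked in
the tests against an independent reference implementation and a bootstrap
oracle. Connection features selected in *every* outer fold form the
consensus-connection set; the full selection-frequency table is emitted so
other cutoffs remain recoverable.

Where the inner-loop protocol of the original MK-SVM formulation is not
fully specified, the choices above (fold counts, linear kernels, simplex
step, threshold-0 decisions, every-fold consensus) are exposed as
configuration and documented here as assumptions.

## The synthetic cohort generator

Because no patient data ship with the package, validation rests on a
phantom-cohort generator with known ground truth. Per cohort, each region
draws a base mean from a uniform 2-8 (SUV-like arbitrary units) hyperprior
and a base SD from uniform 0.3-1, giving overlapping but distinct regional
distributions resembling globally normalised uptake. Controls sample every
region from its base distribution (Gaussian by default; a moment-matched
gamma option exercises skewed, strictly positive intensities); cases are
identical except in a chosen set of *affected* regions, whose mean shifts
by `locationShift` SDs and whose SD is multiplied by `scaleFactor`. The
implied truth edge set is every edge incident to an affected region, since
$W_{ij}$ changes iff $P_i$ or $P_j$ changes. Everything is deterministic
under the cohort seed.

What the generator does *not* emulate: scanner physics, attenuation,
smoothing, partial-volume effects, spatial correlation between
neighbouring regions, and between-subject variability of the regional
parameters (subjects within a group differ only by sampling noise).
Passing tests therefore demonstrate correctness of the estimator and the
pipeline under known effects — not clinical performance on real scans.

## Problem sizes used by the test suite

The statistical suites run at desk scale, chosen once as the package's own
test configurations:

* Type-I calibration: five independent 90-region null cohorts, 20 subjects
  per group, pooled rejection rate over the 4005 edges compared against
  $0.05 \pm 3$ binomial SDs.
* Chance-level classification: twenty 12-region null cohorts, 12 subjects
  per group, nested CV (4 outer / 3 inner folds, simplex step 0.5), pooled
  accuracy against the 3-SD binomial band around 0.5.
* Effect recovery: twenty cohorts with 40 subjects per group, 30 regions of
  which 10 are affected with a 1.5 SD shift; KDE grid 96, sparsity grid
  0.10-0.40 step 0.05 with 2 rewired nulls per threshold; models C, G, N
  and C+G+N with 5 outer / 3 inner folds. Checks: C+G+N accuracy above 0.8
  in at least 90% of cohorts, combined-model mean AUC within 0.02 of every
  single-kernel model, and consensus-connection precision against truth
  edges above chance.

The full-size defaults (90 regions, 49 thresholds, 100 nulls, 10x5 folds,
simplex step 0.1) remain the package defaults for real analyses.

## Known limitations

* Reported per-threshold metric values follow the per-graph mathematical
  definitions; published panels aggregated with unstated scalings (e.g.
  modularity summaries far above 1) cannot be reproduced unit-for-unit,
  and no attempt is made to match them.
* The KDE grid and bandwidth rule are fixed per subject; densities with
  very heavy tails may need a larger grid span than the default 3-bandwidth
  padding.
* The t-test feature selection inside the inner CV reuses the outer-training
  mask rather than re-selecting per inner fold; this economises roughly a
  five-fold recomputation and cannot leak outer-test information, but makes
  the inner AUC estimate slightly optimistic as a model-choice criterion.
* Betweenness-based hub sets on small, dense graphs are unstable; the hub
  rule is reported per metric and group rather than combined.
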