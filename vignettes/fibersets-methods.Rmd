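---
title: "Dominant-set fiber clustering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-set fiber clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersets)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where genuinely open design choices were resolved.

## The clustering model

A tractogram is a set of streamlines, each an ordered polyline of 3D
points in world millimetres. The pipeline treats bundle finding as graph
clustering: fibers are nodes, edge weights are exponential affinities of
pairwise fiber distances, and a cluster is a *dominant set* — the support
of a strict local maximizer of $f(x) = x^\top A x$ over the probability
simplex $\Delta^n$. Dominant sets generalize maximal cliques to weighted
graphs: they are internally coherent (high mutual affinity) and
externally separated, and the framework infers the number of clusters
from the data rather than requiring it up front.

Maximizers are found with replicator dynamics,
$x_i \leftarrow x_i \, (Ax)_i / (x^\top A x)$,
which preserves the simplex and never decreases $f$ for symmetric
non-negative $A$. Clusters are extracted greedily ("peeling"): run the
dynamics, take the support $\{i : x_i > \theta \max(x)\}$, remove those
nodes, repeat on the remaining submatrix until fewer than two nodes are
left or no cohesive structure remains. Leftover nodes become flagged
residual singletons, so the output is always a partition.

The two stages differ only in what the nodes and distances are:

* **Stage 1 (within subject):** nodes are fibers resampled to $k$
  points; distance is the symmetrized point-to-point metric $d_{pp}$
  (the minimum over the flipped orientation of the mean of
  index-corresponding point distances). $d_{pp}$ is preferred over the
  mean-closest-point metric here because it is the fiber-space metric
  that tracks the stage-2 landmark distance most closely, keeping the
  two stages mutually consistent, and it is more robust for short fibers.
* **Stage 2 (across subjects):** nodes are bundle medoids; distance is
  the Euclidean distance between full landmark encodings (all $k \cdot n$
  point-to-landmark distances, flip-minimized). Same-subject affinities
  are forced to zero, so no cluster can contain two bundles of one
  subject; clusters spanning every subject are the group-wise bundles.

The landmark encoding is the registration-free ingredient: every entry
is a within-subject point-to-landmark distance, so moving a subject's
fibers *and* landmarks by the same rigid transform leaves the encoding
unchanged (asserted to $10^{-9}$ mm in the tests). Landmarks must denote
the same anatomical structures in the same order for every subject; the
package takes them from a labelled NIfTI volume (ROI centers of gravity)
or a plain JSON/CSV table, and validates the cohort-wide ordering.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_samples` | 12 | points | fiber resampling resolution; bundle results are insensitive over a broad range, 12 keeps the $O(N^2)$ distance step cheap |
| `sigma` | max pairwise distance | mm | affinity normalization; bounds off-diagonal affinities to $[e^{-1}, 1]$ on any dataset scale |
| `theta` | $10^{-5}$ | – | support threshold; very small values act as a noise reducer, larger values over-segment. Must be $< 1$ (at 1 the strict inequality empties the support) |
| `epsilon` | $10^{-7}$ | – | replicator stopping tolerance on $\lVert x_{t+1} - x_t \rVert_2$ |
| `max_iterations` | 10000 | – | safety cap with a warning; dense random affinity matrices occasionally hit it, bundle-structured data does not |
| `tail_fraction` | 0.05 | – | late-cluster pruning; `ceiling(0.05 M)` of the $M$ non-residual clusters are dropped (late dominant sets are rarely meaningful) |
| `alpha` | 0.05 | – | one-sided level for rejecting cohesiveness outliers in the negative tail after quadratic detrending; $\hat\sigma$ is the residual RMS with the mean pinned at 0 |
| `min_fiber_length_mm` | 3 | mm | short-fiber filter, boundary inclusive (exactly 3 mm is kept) |
| `n` landmarks | 50 | – | encoding dimension; too few under-determine fiber shape, more cost $O(k n)$ per fiber |

## Numerical choices

**Tie-broken barycenter start.** The dynamics start from the simplex
barycenter plus a deterministic linear offset of relative magnitude
$10^{-4}$ (`perturbation` in `ds_config()`). The exact barycenter lies on
the fixed subspaces of every affinity-matrix symmetry: duplicate rows,
twin vertices, or equal-weight overlapping cliques trap the trajectory
on saddle points or non-strict maximizer continua whose supports are
unions of clusters rather than clusters. The offset is far below any
data-driven affinity contrast but breaks those exact ties; runs remain
bit-for-bit deterministic. Passing an explicit `x0` disables it.

**Regularized clique mode.** For *unweighted* 0/1 adjacency matrices the
quadratic program famously admits spurious solutions: convex mixtures of
equal-size maximal cliques overlapping in all but one vertex attain the
same objective, and plain replicator dynamics converges to them from
symmetric starts (measured: on 200 random graphs with $n \le 12$, the
first support was a maximal clique only ~26% of the time). Setting
`regularization = 1/2` iterates on $A + \tfrac12 I$, whose strict local
maximizers correspond one-to-one with maximal cliques (Bomze's result);
combined with the tie-broken start this gave 1000/1000 agreement with
exhaustive clique enumeration. The default is 0 — the clustering
formulation with zero diagonal — because for continuous affinities exact
ties have measure zero; the clique mode exists for verification against
graph-theoretic ground truth.

**Transient filtering at support extraction.** With $\epsilon = 10^{-7}$
the dynamics can stop while components that *would* go extinct are still
above $\theta \max(x)$ (their decay ratio can be arbitrarily close
to 1). Within one subject this only blurs a cluster boundary, but in the
cross-subject matrix it can leave two same-subject rows in a support —
structurally impossible for the exact solution, since their mutual
affinity is zero. Cross-subject peeling therefore keeps only the
largest-$x$ row per subject and returns the rest to the pool: the
structural guarantee applied as a noise filter, in the same spirit as the
$\theta$ threshold itself.

**Degeneracy floors.** (i) An all-zero distance matrix resolves
$\sigma \to 1$ (affinity 1 everywhere off-diagonal). (ii) A cross-subject
block whose maximum distance is at float round-off scale (bitwise
near-identical encodings) also falls back to $\sigma = 1$; normalizing by
$10^{-14}$ would amplify pure round-off into $e^{-1}$ affinity contrast.
(iii) Cohesiveness residuals below $10^{-10}$ of the curve scale are
treated as fit round-off, not noise — an exactly quadratic curve rejects
nothing. (iv) Pairwise distances accumulate squared coordinate
differences directly rather than via the $\lVert a\rVert^2 +
\lVert b\rVert^2 - 2ab$ expansion, which loses half the significant
digits near zero and would break the rigid-invariance bound.

**Other resolved choices.** Cubic spline interpolation for resampling
(linear below 4 points), endpoints preserved exactly; hemisphere split is
a strict side test of all points against a single sagittal plane with
ties going to "inter"; the affinity graph is complete (no sparsification
rule is part of the model); only the second fiber is flipped in the
orientation minimum (flipping both is redundant); peeling deletes
rows/columns of the globally computed affinity without re-normalizing
$\sigma$; medoids use the stage-1 metric with ties broken by lowest
index; residual singletons are always dropped by selection; completeness
is the conditional-entropy form $1 - H(K\mid C)/H(K)$ (base-free), with a
pair-counting variant shipped for cross-checking.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline is meant
for: each subject carries the same `n_bundles` bundles inside a sphere
(default radius 50 mm), laid out at Fibonacci-lattice anchors with
smooth, mildly curved centerlines. Each fiber is the centerline plus a
per-fiber constant perpendicular offset (signed Gaussian magnitude along
a random perpendicular direction, so the offset norm is half-normal with
mean $\sigma\sqrt{2/\pi}$ — a Monte-Carlo test pins this down), plus
per-point jitter, with a 0.5 probability of reversed point order.
Subjects are rigid copies: one canonical subject is drawn, then each
subject applies its own rigid transform to fibers *and* landmarks
(Fibonacci shell at 0.9 radius), optionally followed by per-subject point
noise. Ground-truth bundle identity and cross-subject correspondence are
exact by construction. The RNG layout is documented (canonical subject
from `seed`, landmarks from `seed + 777`, subject $s$ from
`seed + 10007 s`) so adding subjects never perturbs earlier draws, and
bundle placement is validated against a separation constraint
(`separation_factor` × `cross_section_sd`, default 6) with an explicit
infeasible-packing error.

What the generator does **not** emulate: crossing and broken fibers,
length heterogeneity within a bundle, partial-volume and low-anisotropy
tracking artifacts, non-rigid anatomical variability, or any diffusion
signal model. Passing tests therefore demonstrate that the machinery
recovers planted structure under rigid inter-subject variability and
Gaussian within-bundle noise — not that it segments real tractography
perfectly.

Two behaviours of the method itself are worth knowing when reading test
results. First, with $\sigma = \max$ on a *single* large homogeneous
bundle, dominant sets extract a tighter core rather than the whole
bundle (measured 47–68% of 40 fibers, versus 100% of 12): concentrating
mass on an above-average-affinity subset beats the $1/n$ uniform payoff
once $n$ is large. In multi-bundle data the inter-bundle distances
inflate $\sigma$, within-bundle affinities become near-uniform, and
bundles are recovered whole — the regime the method targets. Second, the
ranking of the four streamline-by-landmark metric correlations is a
knife edge on this generator's rigid-copy cohorts: both landmark
encodings correlate with $d_{pp}$ above 0.999, with the min-landmark
variant ahead of the full encoding by about $2\times10^{-4}$. Bundle
size and landmark count move this ordering (a 6-bundle, 20-landmark
subject puts the full encoding first); the stage-2 default remains the
full encoding, whose higher-dimensional geometry is what degrades
gracefully for similar-but-distinct bundle shapes.

## Problem sizes and runtime

The test suite and the acceptance script run, in well under a minute
each on one CPU: stage-1 recovery on a 500-fiber subject (10 bundles ×
50 fibers), cross-subject matching on 4 subjects × 8 bundles (clean and
with 0.2 mm per-subject jitter), 100 random 5–50-node affinity matrices
for the replicator invariants, 200 random ≤ 12-node graphs against
exhaustive clique enumeration, and 1000 random rigid-invariance triples.
The distance step is dense $O(N^2 k)$; a 15k-fiber hemisphere is feasible
but takes minutes and ~2 GB for the matrix, which is why hemisphere
splitting (`split_hemispheres = TRUE`) exists in the pipeline
configuration.

## Known limitations

* $O(N^2)$ distance and affinity matrices by construction; no
  approximate nearest-neighbour shortcut is provided.
* Landmarks are assumed already in each subject's space; atlas-to-subject
  registration is out of scope.
* No out-of-sample assignment: adding a subject means re-running stage 2.
* Anatomical naming of matched bundles is up to the user.
* The TCK reader/writer covers Float32LE tracks (the common case); TRK
  is not parsed — convert externally or use the CSV interchange format.
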