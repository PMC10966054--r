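---
title: "Shape-graph topology of multi-state brain dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-graph topology of multi-state brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statemapper)
```

# The analysis this package implements

`statemapper` treats a preprocessed multi-state recording — a frames ×
features matrix in which every frame carries one of six state labels
(focused attention FA, open monitoring OM, resting state RS, each in a
pre- and a post-intervention session) — as a point cloud in "activation
space" and compresses it into a **Mapper shape graph**:

1. **Filter.** A 2-D lens embedding of the frames. The lens is only used to
   slice the data; all clustering happens in the original feature space.
2. **Cover.** The lens image is covered by a `b × b` grid of overlapping
   rectangles (defaults `b = 30`, overlap `p = 0.5`). Per dimension the base
   width is `(max − min)/b`; interval *i* is centred at
   `min + (i + ½)·base` with half-width `base·(1+p)/2`.
3. **Partial clustering.** Each bin's preimage is clustered with a
   density-based (DBSCAN-style) rule in the original space, using a single
   global radius ε: the smallest value such that every frame has at least
   `k = 3` neighbours within ε.
4. **Graph.** One node per cluster; an edge whenever two clusters share a
   frame (possible because bins overlap). Noise points become singleton
   nodes so no frame is ever lost.

On the resulting labeled graph the package computes, per subject:

* the **state distribution** μ_l: per node, the within-node proportion of
  label-l frames, normalized across nodes to sum to 1;
* the exact **1-Wasserstein (optimal-transport) distance**
  d_OT(μ_l, μ_k) = min over couplings of Σ D_ij μ_ij, with D the
  node-to-node geodesic (hop-count) matrix;
* μ_l-weighted **closeness** and **degree centrality**, and the **label
  diameter** (longest geodesic between two l-nodes).

A statistics layer mirrors the two-group pre/post design: mixed two-way
ANOVA (group ×
session), Welch and paired *t* tests with Benjamini–Yekutieli FDR across
the post-hoc family, Kendall and Pearson correlation matrices corrected by
an effective number of tests (Nyholt's eigenvalue-variance estimator, the
Li–Ji variant behind a flag), random-intercept mixed linear models with
marginal/conditional R², a median-split paired test, and a linear model of
insightfulness on derealization and d(OM1, OM2).

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bins` (b) | 30 | cover divisions per lens dimension |
| `overlap` (p) | 0.5 | fraction of base width shared by adjacent intervals |
| `k` | 3 | neighbour count in the global ε rule |
| `min_neighbors` | 2 | other points within ε needed for a DBSCAN core |
| `filter_method` | linear-projection | lens; `identity` and `nonlinear-manifold` available |
| `window` | 100 | frames kept per state block (centred) |

With n = 600 frames, the expected points per non-empty bin is
`n / ((b + p − bp)² (1 − f_empty))`; at `b = 30`, `p = 0.5` and 40% empty
bins this is ≈ 4.16 — a deliberate operating point: enough shared points to
create edges, few enough to retain fine structure
(`expected_points_per_nonempty_bin()`).

**Why `min_neighbors = 2`.** The common DBSCAN convention (`min_samples`)
counts the point itself, so "minimum 3 samples" means two *other*
neighbours. This package's `min_neighbors` counts other points only. At the
operating density of ~4 points per non-empty bin a threshold of three
*others* leaves most bins unable to form any core — the shape graph then
degenerates into per-frame singletons for *any* input geometry — so the
default is 2 (i.e. the conventional `min_samples = 3`), while the ε rule
stays at `k = 3`.

**Filter choices.** The default lens is the deterministic top-2
variance-maximizing projection, with eigenvector signs fixed canonically so
identical inputs give identical embeddings. The stochastic
nonlinear-manifold lenses common in this field (UMAP and relatives) are
represented by a deterministic neighbour-graph spectral embedding (Laplacian eigenmaps of
the kNN graph, with an MST union so the graph is connected): the package
deliberately does not re-implement UMAP, and no R implementation is part of
its dependency footprint. The filter is pluggable behind one contract, so a
different lens can be substituted without touching the rest of the
pipeline.

**Epsilon is global.** ε is computed once on the full concatenated cloud,
not per bin: a single stated rule, and node composition that does not
depend on bin occupancy.

**Disconnected graphs.** Real Mapper graphs fragment. Distances are only
defined within a component, so `compute_all_measures()` restricts the
analysis to the component carrying the largest number of frame memberships
and reports the discarded mass fraction per subject; state labels absent
from that component yield `NA` measures rather than silent infinities.

# Exact optimal transport, twice

The 1-Wasserstein distance is solved exactly, never by entropic
regularization, via two independent routes:

* `ot_distance(D, p, q)` — a dense transportation simplex (u–v/MODI method)
  on the support-restricted cost matrix; returns the optimal coupling.
* the cohort pipeline — an uncapacitated min-cost flow on the graph itself
  (successive shortest paths with integer Johnson potentials and a bucket
  Dijkstra), linear in the number of edges per augmentation.

The two routes agree to 1e-9 by construction and are property-tested
against each other and against an independent pure-R two-phase simplex
oracle on every connected graph with up to six nodes (the test suite's
acceptance criteria 2–3).

# What the synthetic cohort emulates — and what it does not

Multi-subject neuroimaging recordings of this kind are rarely shareable,
so the package ships a seeded generator (`generate_cohort()`) whose
defaults *are* the stated world of the tests: 18 subjects per group, six
concatenated 100-frame state blocks (RS, FA, OM per session, scan order),
200 features.

The generative geometry lives in a low-dimensional latent space embedded
orthonormally in feature space:

* the three **condition means** sit at the vertices of an equilateral
  triangle (side `state_separation = 1.5`) in latent dims 1–2;
* the **retreat** shifts the whole session-2 triangle along an orthogonal
  axis `u` (`retreat_shift = 1`), scaled per subject by a gain
  `~ N(1, retreat_gain_sd = 0.2)`;
* the **drug** displaces OM2 along `+w` and RS2 along `−w` (a fourth
  orthogonal axis) by `drug_shift_scale = 1.5` times a subject latent
  (active group `~ N(1, 0.35)`, control `~ N(0, 0.1)`). The opposite signs
  are a deliberate design choice: a common displacement of both states
  would leave their mutual distance unchanged and could not plant the
  group effect on d(OM2, RS2) that the pipeline is meant to recover;
* **noise** is AR(1) in time (coefficient 0.4, continuous within a session,
  restarted at the session boundary) and confined to `n_noise_modes = 10`
  orthonormal spatial modes with geometrically decaying scales (ratio 0.7),
  total innovation energy matched to isotropic noise of sd `noise_sd`.

Low intrinsic dimensionality is the load-bearing choice. Preprocessed BOLD
frames live near a low-dimensional manifold, which is why lens proximity
implies activation-space proximity and why bin-wise clustering can merge
frames across states and sessions. An early isotropic-noise,
mutually-orthogonal-state variant of this generator produced shape graphs
whose components never mixed states — 40–70% of node mass fell outside the
largest component and no planted effect survived, at *any* effect size.
In that world no shape-graph analysis of state similarity is possible at
all, which is why the variant was rejected as unrealistic.

Psychometrics are generated as noisy linear readouts: positive
derealization from the drug latent, insightfulness from derealization plus
the subject's realized retreat-response magnitude (coefficients retained in
the output for recovery tests). The per-subject retreat gain exists
precisely so that d(OM1, OM2) carries subject-level information — without
it the insightfulness model's distance term would be a constant.

Effect sizes were calibrated once, on pilot seeds disjoint from the test
seeds, to the weakest setting at which the planted OM2/RS2 group effect is
reliably detectable at n = 18/group (Welch rejection ≈ 0.9, Kendall τ > 0
throughout, null rejection at nominal level), and then frozen. The
generator does **not** emulate: hemodynamics, spatial smoothness or voxel
geometry, motion or physiological artifacts, non-stationary state
transitions, or the retreat-induced *decrease* of d(FA, OM) and the OM
centrality increase reported for the real data — a green end-to-end test
therefore establishes that the pipeline recovers planted geometry, not
that it reproduces every empirical finding.

# Numerical and procedural choices

* **Geodesics** use unit edge weights (hop counts); unreachable pairs carry
  an explicit `Inf`, and transport across components raises an
  `infeasible-transport` error rather than returning infinity.
* **Closeness** of a node is (number of reachable other nodes) / (sum of
  geodesic distances to them); isolated nodes score 0; no small-component
  rescaling.
* **Degree centrality** is degree / (N − 1); it errors on a single-node
  graph instead of inventing a normalization.
* **μ_l** uses within-node label proportions (pie-chart semantics);
  a count-based variant is available via `mode = "count"`.
* **Welch by default** for independent-samples *t* tests: the planted drug
  effect inflates the active group's variance, so the unequal-variance form
  with fractional degrees of freedom is the right default.
* **Median split** assigns ties — including the median element — to the
  lower group, so odd cohorts split `⌈n/2⌉ / ⌊n/2⌋`.
* **Mixed models** are REML random-intercept fits; *t* and *p* values use
  containment degrees of freedom; marginal R² is var(Xβ) over total
  variance, conditional R² adds the intercept variance. Singular fits are
  flagged and refitted as plain linear models.
* **Family corrections**: ×3 across {cc, dc, diam} per condition;
  BY-FDR across the post-hoc *t* family; ×M_eff for the psychometric
  battery, with M_eff computed from the battery's own correlation matrix
  (never hard-coded).
* **Determinism**: every stochastic step takes an explicit seed; subject
  streams are derived from (seed, subject index, group) with a fixed
  integer hash, so any subject can be regenerated in isolation.
* **Window slicing** generalizes "the middle 100 of 210 frames" as
  start = ⌊(L − w)/2⌋ per block.

# Known limitations

* The per-subject shape graph typically keeps ~70% of node mass in its
  largest component at the synthetic defaults; subjects whose OM2 or RS2
  nodes fall outside it contribute `NA` distances (3–4 of 36 subjects per
  cohort, handled by the NA-aware tests).
* The nonlinear-manifold lens is a spectral stand-in with the same
  contract as the original stochastic embedding, not a reimplementation.
* Closed-form expectations for the bin-density formula assume a uniform
  lens occupancy; real occupancy is skewed, so the formula is an operating
  guide, not a prediction.
* The statistics layer assumes the balanced two-session design; the
  two-level within factor makes sphericity corrections moot.

# A minimal run

```{r example, eval = FALSE}
cfg <- run_config(params = cohort_params(seed = 1), out_dir = "results")
res <- run_cohort(cfg)
head(res$measures[, c("subject_id", "group", "d_OM2_RS2", "dc_OM2")])
res$stats$kendall
```
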