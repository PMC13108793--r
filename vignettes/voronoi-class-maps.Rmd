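---
title: "Voronoi class maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi class maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VoronoiClassMap)
```

## The problem

Two-dimensional score plots of projected biomedical data (PCA, PLS-DA,
or raw 2-D coordinates) are conventionally annotated with per-group
confidence ellipses. Ellipses summarize each group's distribution but
can hide individual cases that project into the territory of another
group. This package draws the projection plane as a *class map*: the
Voronoi tessellation of the points, each cell colored by the class of
its generating point, like a political map. A case that sits among
foreign-class neighbors is then immediately visible, and the structure
can be quantified by a metric that is intrinsic to the tessellation: the
**Voronoi island count**.

## The model and its pieces

### Bounded Voronoi tessellation

Given distinct points $p_1,\dots,p_n$ in the plane, the Voronoi cell of
$p_i$ is

$$V_i = \{\, x : \lVert x - p_i \rVert \le \lVert x - p_j \rVert
  \ \text{for all}\ j \ne i \,\},$$

with Euclidean distance. A plot panel is finite, so the tessellation is
computed over a rectangular window: the data bounding box expanded by
`margin_frac` (default 0.05) of each axis range per side; a zero-range
axis is expanded by 1.0 absolute units. Each cell is built exactly as
the intersection of the window rectangle with the half-planes bounded by
the perpendicular bisectors towards the other points
(Sutherland–Hodgman clipping). Bisectors are applied in order of
increasing center distance, and clipping stops once half the distance to
the next center exceeds the farthest current cell vertex — the remaining
bisectors provably cannot cut the cell — so the construction is fast
enough for hundreds of points in pure R. Cell areas consequently sum to
the window area exactly (relative tolerance $10^{-6}$ in tests), which
is the invariant the test suite checks against a brute-force
nearest-center rasterization.

### Neighbor graph and islands

Two points are *Voronoi neighbors* when their clipped cells share a
boundary segment of positive length (longer than $10^{-9}$ times the
window diagonal). This is the Delaunay-dual relation restricted to the
window; degenerate cocircular configurations whose dual edge has zero
length — e.g. the diagonals of four points on a square — are not
neighbors, which makes the relation deterministic. Adjacency is read off
the finished cells: each cell edge's midpoint is equidistant from the
two owning centers and strictly closer to them than to any other center,
so attributing edges by a midpoint distance scan recovers the dual graph
without extra geometry.

A point is a **Voronoi island** when it has at least one neighbor and
*none* of its neighbors shares its class label. The island count and the
island rate (count divided by $n$, printed as a percentage rounded
half-up to one decimal) summarize the strongest local class-discordance
signal. Two discordant same-class points that are adjacent to each other
are deliberately *not* islands — each keeps a same-class neighbor — so
the metric measures complete local isolation, not general spatial
mixing. On a plot the count is always computed on the classification
that fills the cells (the `fill_voronoi` choice), never the point-color
classification, so the subtitle describes the map actually shown.

Because the window is finite, two hull points whose unbounded cells
would meet far outside the plotted panel are not neighbors here. Island
status of extreme hull points can therefore differ from an unbounded
treatment; we consider the clipped behavior the right one for a metric
that describes the visible plot.

### Confidence ellipses

For a group with mean $\mu$ and covariance $\Sigma$ the ellipse is
$\{x : (x-\mu)^\top \Sigma^{-1} (x-\mu) \le c\}$ with $c$ the
chi-squared (df = 2) quantile at the chosen level
($c = -2\ln(1-\text{level})$; 5.9915 at 95%). The sample covariance
(divisor $n-1$) is used, giving a *data* ellipse — a region for
observations — which is what standard score-plot ellipses show and what
the inequality above describes with no $1/n$ factor. A mean-coverage
variant ($\Sigma/n$) is exposed via `type = "mean"` for users who want
the confidence region of the group centroid instead. Groups with fewer
than three points or a singular (collinear) covariance are skipped with
a warning so the rest of the plot still renders.

### Projections

`pca_scores()` is the SVD of the centered (optionally autoscaled)
matrix. `plsda_scores()` regresses a centered one-hot class indicator on
the autoscaled features with the iterative NIPALS PLS2 algorithm
(convergence tolerance $10^{-9}$ on the score vector, at most 500
iterations per component, deflation of both blocks). The algorithm
variant is not dictated by the visualization method — any supervised
2-D projection works — and was fixed for determinism. Both projections
share a sign convention (the largest-magnitude loading entry of each
component is positive), so scores, plots and island counts are
reproducible; other implementations may differ by reflection, which does
not affect the tessellation's adjacency structure. A cross-check test
confirms the first component agrees with an independent PLS-DA
implementation up to such a reflection.

## Synthetic benchmarks

The generators reproduce the study conditions under which the island
metric was characterized; all of them take a `seed` and return
bit-identical data for the same seed.

* **Two-class** (`gen_two_class`): $n = 80$, classes 40/40, nine
  features named A, B, C, D, E, G, H, I, J. A is Normal with class
  means (4, 8) and unit SDs — a separation of 4 pooled SDs, so the
  classes form two clean clouds. B inverts the relationship
  ($N(0.3\mu_1, 0.9\sigma_1^2)$ for class 1, $N(0.5\mu_2,
  0.9\sigma_2^2)$ for class 2). E and G are class-banded uniforms
  $U(\mu_i - 1 + u,\ \mu_i + 1 + u)$ with one jitter
  $u \sim U(-0.25, 0.25)$ per class and variable. C and D draw from the
  integers 1–10 with weights $\propto \text{position}^{\text{class
  index}}$ plus $N(0, 0.1)$ jitter — moderate separation with overlap.
  H is $U(0, 10)$ for everyone, $I = 0.8H + 1 + N(0, 0.3)$, and J is
  pure $N(0, 1)$ noise completing the nine columns. The lettering skips
  F, and only eight constructions are fully pinned down by the original
  description, so the ninth column was fixed here as pure noise.
* **Label switch** (`flip_labels`): exactly `k_per_class` (default 3)
  uniformly chosen cases per class get the opposite label; features are
  untouched and the flipped indices are recorded in `meta$flipped`.
  Selection is stratified by the labels *as generated* (kept in
  `meta$base_labels`), so the same seed selects the same cases again:
  applying the operation twice with one seed is a true involution that
  restores the original labels. Stratifying by current labels instead
  would break that reversibility, because the first flip changes the
  class memberships the sampler would draw from.
* **Three-class** (`gen_three_class`): $n = 75$, classes 20/40/15, A
  Normal with means (4, 6, 8) and SDs (2, 4, 3), the other features
  built as in the two-class case with class index 1–3. For B, "scaled
  versions of the same parameters" was fixed as both the means and the
  SDs scaled by 0.5 (keeping the 0.9 variance shrink):
  $B \sim N(0.5\mu_i,\ 0.9\,(0.5\sigma_i)^2)$. This preserves A's
  standardized group separation, so B is reliably rank-test significant
  (~98% power at these sample sizes), matching the intended
  informative/noise split of the variables: A, B, E, G carry class
  signal; H, I, J do not. Scaling only the means (the two-class
  factors verbatim) would leave B with ~42% power — an effectively
  ambiguous variable, which is not the role B plays.
* **Permuted variant** (`permute_to_nonsignificance`): every column
  independently permuted; any column whose Kruskal–Wallis p-value
  against the unchanged class vector is still ≤ 0.05 is re-permuted (at
  most 100 attempts, practically never more than a few). The output is
  guaranteed non-significant in all nine variables while every column
  keeps its exact marginal distribution.
* **Lsun-style** (`gen_lsun`): 400 points, three classes with unequal
  geometry — a horizontal brick $U([0,6]\times[0,0.8])$ (150 points), a
  vertical brick $U([0,0.8]\times[1.3,4.3])$ (150), and an isotropic
  Gaussian disk (SD 0.3, truncated at 3 SD, center (3.5, 3), 100
  points). Per-class sizes are not published for the original benchmark;
  150/150/100 keeps the bricks dense enough that single-linkage chains
  never break. All inter-class gaps exceed 0.2 times the smallest
  rectangle side, so single linkage recovers the classes exactly
  (adjusted Rand index 1.0), while the elongated bricks violate
  k-means' spherical assumption: with $k = 3$ and 100 restarts k-means
  cuts the long brick instead (ARI ≈ 0.6–0.85 across seeds in the
  test suite).

### What the generators do and do not emulate

They emulate controlled class geometry: known separation on named
variables, known label noise, known cluster shapes. They do not emulate
features of real biomedical tables — correlated feature blocks,
heavy-tailed measurement noise, batch effects, missingness — so passing
tests show that the geometry, metric and pipeline behave as specified
under clean conditions, not that island counts on any particular real
dataset will match. Island counts also depend on the projection
implementation: a different PLS-DA variant can move boundary cases in
or out of island status.

## Benchmark experiment sizes

The label-switch experiment (generate, flip 3 per class, PLS-DA on the
modified labels, tessellate, count islands) uses 50 replicate seeds,
enough to stabilize the median island rate; the clustering contrast uses
20 seeds with 100 k-means restarts each; ellipse coverage uses 10,000
bivariate normal draws. These sizes were chosen so the entire suite runs
in well under a minute on one core while keeping the Monte-Carlo error
far below the decision margins (e.g. the coverage check's binomial SD is
0.002 against a ±0.01 band).

## Numerical choices

* Duplicate points (within $10^{-9}$ relative tolerance) are a hard
  error naming the case ids; duplicate centers make ownership undefined
  and silently merging them would silently change $n$ and the rate.
* `locate()` breaks boundary ties towards the lowest point index.
* Clipping uses an epsilon of $10^{-12}$ window diagonals; adjacency
  attribution tolerates $10^{-7}$ diagonals of midpoint-equidistance
  error. Both are far below the edge lengths that occur in data and far
  above double-precision noise on the bisector intersections.
* Rates are rounded half *up* (away from zero) at one decimal:
  2/72 → 2.8%, 4/72 → 5.6%, 4/80 → 5.0%. Banker's rounding would
  render some of these differently.
* The default palette is the 8-color Okabe–Ito colorblind-safe cycle
  (without black); beyond 8 classes it recycles with each further cycle
  lightened 30% towards white, deterministically. Label placement uses
  greedy radial offsetting (eight compass directions, growing radius) —
  cosmetic only, no collision library required.

## A worked example

```{r example, eval = FALSE}
ds <- gen_two_class(seed = 1)
dsf <- flip_labels(ds, k_per_class = 3, seed = 2)
proj <- plsda_scores(ds$X, dsf$y)

d <- data.frame(proj$scores, class = dsf$y)
res <- create_tessellation_plots(
  d, class_column = "class",
  coordinate_columns = c("Component 1", "Component 2"),
  show_island_count = TRUE, label_islands_only = TRUE)
res$islands
res$combined_plot
```

The island report lists which of the label-switched cases ended up
entirely enclosed by the opposite class; typically 3–5 of the 6 flipped
cases qualify, the rest landing close enough to their feature-matched
group boundary to keep one same-class neighbor.

## Known limitations

* Only 2-D tessellations, Euclidean distance, rectangular windows.
* The island metric flags single-cell isolation; small same-class
  enclaves of two or more mutually adjacent cells are not counted, by
  definition.
* No significance machinery for island counts — there is no agreed null
  model, so the count is a descriptive, visualization-intrinsic metric.
* UMAP or any other external projector is supported only by passing its
  2-D coordinates in as data.
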