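---
title: "Intelligent dasymetric mapping with dasypop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intelligent dasymetric mapping with dasypop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasypop)
```

## The model

Population counts $y_b$ are recorded in irregular source units $b$
(census blocks). `dasypop` estimates a per-cell density surface on a
regular equal-area grid by assuming that, within a processing zone,
population density is homogeneous within each class of a class-coded
ancillary raster (land cover plus one reserved *uninhabited* class). The
atoms of allocation are *target units*: the intersection of one source
unit with one ancillary class, with area measured as the rasterized cell
count $A_t$, so all densities are in persons per cell (900 m² at the 30 m
convention).

Each class $c$ in each zone receives a representative density
$\hat D_c$ by a three-tier rule:

* **preset** — the uninhabited class and, by default, open water,
  perennial ice/snow, and emergent herbaceous wetlands are fixed at zero;
  user overrides (e.g., replacing an implausible estimate with a density
  borrowed from other zones) are also presets and take precedence over
  everything;
* **sampled** — for classes with at least `minSamples` *representative*
  units (coverage $\ge$ `coverageThreshold` in the class and at least
  `minCells` cells), the ratio of sums
  $\hat D_s = \sum_b y_b / \sum_b A_b$. The ratio of sums — not a mean of
  per-unit ratios — is what makes large empty units dilute the estimate
  correctly;
* **intelligent areal weighting (IAW)** — for everything else, each
  unit's residual $G_b = y_b - \sum_k \hat D_k A_{t(k)}$ over
  preset/sampled classes $k$ (clamped to zero when negative, so no target
  is ever assigned negative population) is spread over the unit's
  unsampled targets by area, and $\hat D_i$ is the zone-wide ratio of
  those initial estimates to their cells. This is a single pass, not a
  fixpoint iteration.

Final allocation weights each target by $A_t \hat D_{c(t)}$ and rescales
to the unit total, so $\sum_t \hat y_t = y_b$ — the pycnophylactic
property — holds for every unit by construction. A populated unit whose
every class has zero density (it can happen: a block entirely water plus
uninhabited) falls back to pure areal weighting rather than losing its
people. Cell densities are $\hat d_t = \hat y_t / A_t$.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `coverageThreshold` | 0.95 | fraction | homogeneity bar for sampling; inclusive at the bar |
| `minCells` | 2 | cells | rasterized area strictly greater than one pixel |
| `minSamples` | 3 | units | representative units before a class counts as sampled |
| slope threshold | 25 | % slope | cells strictly above are uninhabited |
| mixed-use rule | 0.90 | fraction | strict block-coverage bar for mixed-use features |
| total rule | 0.99 | fraction | strict block-coverage bar for all features |
| line buffers | 15 / 30 | m | rail / aircraft-road centerline widths |
| rail yards | 500 / −480 | m | buffer then erode "YARDS" rail lines, dissolving in between |

The two coverage rules exist for opposite reasons: mixed-use categories
(malls, retail, industrial) may house people above street level, so when
they dominate a block (> 90%) they are distrusted and dropped *within
that block only*; and any block almost entirely (> 99%) covered by
uninhabited features would strand its recorded population, so there the
features yield. Both rules act on vector areas, before rasterization, and
a feature spanning several blocks keeps its parts in blocks that trigger
neither rule.

## Geometry and numerical choices

Vector geometry (buffers, erosions, boolean ops, dissolves) runs on the
Vatti clipping engine in `polyclip` at a fixed resolution of $10^{-6}$ m
anchored at the origin: metre-aligned fixture coordinates survive integer
snapping exactly, which is what makes exact-boundary tests (a feature
covering *exactly* 90% of a block) meaningful. Threshold comparisons add
a $10^{-9}$ absolute guard on computed fractions so snapping noise can
never flip a strict inequality; every distinction the method relies on is
at least $10^{-3}$ wide.

Rasterization uses the cell-center rule: a cell belongs to the polygon
containing its center, boundaries inclusive, and a center lying exactly
on a boundary shared by two units goes to the smaller unit id. The tie
rule is declared, not inferred from any upstream implementation — it
makes rasterization deterministic under input reordering. All rasters in
a run must share one `GridSpec`; resampling and reprojection are out of
scope, and a geographic CRS is rejected rather than silently reprojected.

Units too small or awkwardly placed to contain any cell center would
silently lose their population, so populated ones are first dissolved
into the same-tract neighbor with the longest shared border, preferring
populated neighbors and falling back to unpopulated ones; ties go to the
smaller unit id, and merging iterates to a fixpoint because a recipient
can itself be unrepresented. Shared border length is the exact collinear
overlap of boundary segments, so point-touching neighbors never qualify.
A donor with no same-tract neighbor at all stays in place and its
population is reported as unallocatable rather than displaced across a
tract boundary.

Ratio-of-sums accumulations use R's long-double summation; the declared
tolerance for all pycnophylactic checks is $10^{-6}$ relative, and in
practice the observed error is at machine precision ($\sim 10^{-16}$).
The tract-identity assessment (below) is asserted at $10^{-9}$: the
allocation round-trips through per-cell densities
($A_t \cdot (\hat y_t / A_t)$), so exact bitwise zero is not attainable
in floating point, but the residual is $\sim 10^{-14}$ persons.

## Scale-up cross-validation

Block-level estimates equal the census counts by construction, so they
cannot validate the density tables. Instead, blocks are aggregated to
tracts (population summed exactly; the tract raster is the block raster
relabelled by tract id, which keeps the two levels exactly nested
cell-for-cell), the tracts are disaggregated using the block-run density
table as presets for every class — no resampling at tract level — and
the recovered block populations are scored with

$$\mathrm{MAE} = \tfrac1n \sum_b |y_b - \hat y_b|, \quad
  \mathrm{RMSE} = \sqrt{\tfrac1n \sum_b (y_b - \hat y_b)^2}, \quad
  \mathrm{NRMSE} = \mathrm{RMSE} / \bar y$$

pooled per state, per county, and domain-wide (county summaries reuse the
state-zone run; blocks merged away in preparation are assessed at their
recipient). When the mean population of a summary unit is zero, NRMSE is
reported missing, not infinite. With tracts identical to blocks the
design degenerates to an identity and all metrics vanish — a useful
self-consistency check.

## What the synthetic generator emulates

`syntheticScenario()` builds landscapes whose truth matches the
estimator's core assumption: each cell carries the true density of its
class (zero inside designated uninhabited-truth polygons), and block
populations are the rounded — or Poisson-drawn — sums of their cells'
truth. Blocks are cell-aligned rectangles (so cell-center membership is
analytically checkable), with nested tract/county/state ids, an optional
count of fully homogeneous blocks per class to feed the sampler, and
optional populated sub-pixel blocks carved out of hosts to exercise the
merge step. One seed governs all draws in a documented order (patches,
slope, block roles, populations), so identical specs regenerate
byte-identical fixtures.

Default conditions: a 60 × 60 grid of 30 m cells, five land-cover-like
classes with true densities 0 (water), 2 and 5 (developed), 0.1 (forest),
0.05 (shrub) persons per cell, a 6 × 6 block tessellation (~100 cells per
block), three homogeneous blocks per class, and 2 × 2 blocks per tract.
These are plausible magnitudes for 30 m census-block data (5 persons per
900 m² cell is a dense urban block) and are deliberately modest in size:
the property suites run hundreds of scenarios on one CPU in seconds, and
the statistical bounds they assert (recovery within $1/\min_b A_b$
deterministic, within 3 standard errors Poisson) do not sharpen with
larger grids.

What passing tests on these landscapes show — and do not show: they
verify the estimator's algebra, its conservation guarantees, the
selection and precedence logic, and the directional value of masking
truly uninhabited land. They do not certify performance on real census
data, where within-class density is *not* homogeneous, block geometries
are not rectangles, ancillary classes are misclassified at some rate, and
uninhabited layers carry temporal mismatch — failure modes the
cross-validation design is meant to surface on real inputs.

## The worked example

`workedExampleFixture()` is a fixed one-tract, six-block scene with two
classes (5.0 and 0.2 persons per cell) and one cemetery covering 80% of a
block; its truth places that block's people along the uncovered strip,
and block populations are perturbed by deterministic ±10% multipliers so
that neither specification can reproduce them exactly. Running the tract
assessment with and without the cemetery mask shows the point of the
uninhabited specification: the tract MAE falls from 124.5 to 25.6
persons per block, masked cells get exactly zero density, the habitable
strip gets denser (5.5 vs 1.1 persons per cell), and every block total is
untouched. The populations are chosen by this package and documented in
the fixture; only the *direction* of the comparison is the scientific
claim.

## Design decisions taken where the method is open

* Coverage fractions for the 90%/99% exclusion rules are computed on
  post-residential-clip vector geometry, in the order clip → mixed-use
  rule → total rule → dissolve; overlapping features are unioned first so
  overlaps are not double-counted.
* "YARDS" matching is a case-insensitive substring on the name field.
* Buffers use round caps and joins.
* The homogeneity comparison at exactly 95% is inclusive; the slope rule
  at exactly 25% and the coverage rules at exactly 90%/99% are strict.
* The uninhabited class code defaults to one more than the largest
  land-cover code, configurable, and colliding with an existing code is
  an error.
* Zone merging (small zones processed with a neighbor) is a declared map;
  a single-zone run is the national-analysis limit.
* The CONUS-style pooled domain metric pools blocks rather than averaging
  per-state metrics.

## Known limitations

No uncertainty is attached to $\hat D$; covariate or regression
dasymetrics and multi-temporal modelling are out of scope. Slope is
consumed, never computed from elevation. The package neither reprojects
nor resamples; inputs must already share one equal-area grid. IAW is the
single-pass formulation, which can leave residual structure when many
classes in a zone are unsampled.
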