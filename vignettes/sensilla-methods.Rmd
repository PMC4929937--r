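---
title: "Quantifying and reconstructing scale-sensilla coverage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and reconstructing scale-sensilla coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensquad)
```

`sensquad` turns labelled images of a snake's postocular scale region into
three morphometric traits — numerical density of sensilla (mm⁻²), mean
sensillum size (µm²) and percentage coverage — and analyses those traits
on a time-calibrated phylogeny with independent contrasts and a
Brownian-motion (BM) ancestral-state reconstruction. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the package's synthetic ground truth does and does not establish
about real data.

## The counting-frame estimators

A scene is a 16-bit label raster: background 0, every sensillum one
8-connected blob of a distinct positive label, and a reserved label
(65535) for a rendered scale bar. Physical calibration comes either from
an explicit `mm_per_px` in the JSON sidecar or from the scale bar, whose
pixel length is taken as the longest horizontal run of bar-labelled
pixels; runs shorter than 10 px are rejected as unreliable. The region of
interest (roi) is rasterized from a rectangle, ellipse or polygon
description in the sidecar, or read from a second image channel.

`build_grid()` tiles the roi bounding box with congruent square cells of
side `round(sqrt(roi_area_px / target_cells))`, anchored at the bounding
box's top-left corner, and keeps only cells that lie entirely inside the
roi. "Approximately 100 cells" is therefore a target, not a guarantee: a
disc-shaped roi yields fewer. Keeping only whole cells makes the summed
cell area `A_c` unambiguous; partial boundary cells would otherwise
contribute ill-defined area. `select_cells()` implements systematic random
sampling in raster order: with `n` cells and sample size `k` (default 10),
the stride is `floor(n/k)` and the start offset is drawn uniformly from
`[0, stride)`; the seed is mandatory and recorded so a run can be
replayed exactly.

Counting uses the unbiased counting frame with the top and right edges
forbidden: an object crossing a cell's top or right edge is excluded from
that cell and picked up by the neighbour above or to the right. In pixel
space the package implements the rule in its band-owner form: an object
belongs to the cell whose row band contains the object's topmost pixel and
whose column range contains its rightmost pixel within that band. Both
forbidden-edge exclusions follow from this (a top-edge crosser has pixels
above the band; a right-edge crosser has band pixels beyond the last
column), and — unlike a literal "adjacent pixel pair across the edge"
test, which an 8-connected object can evade by slipping diagonally across
a cell corner — the band-owner form assigns every compact object to
exactly one cell, so a full-tiling sweep conserves the census count
exactly. The test suite verifies this conservation on simulated scenes.

Estimators, for `k` selected cells of side `s` px with pixel size `m`
mm/px: `A_c = k (s m)²`; `N_s` is the number of distinct objects included
over the selected cells (an object included in two selected cells counts
once); `A_s` is the summed **full** pixel area of the included objects
times `m²` — objects are not clipped to cells, so mean size estimates the
whole organ's area. Then density `= N_s / A_c`, mean size
`= 10⁶ A_s / N_s` (µm²; reported missing when `N_s = 0`, never zero), and
coverage `= 100 A_s / A_c`, giving the exact identity
`coverage = density × mean_size × 10⁻⁴`. Species are summarized by the
arithmetic mean and the standard error of the mean (sd with `n − 1`
denominator over √n); with a single specimen the sem is reported missing
rather than zero.

## Contrasts, allometry and the F test

Traits are log₁₀-transformed (the package refuses non-positive values)
and converted to standardized independent contrasts by post-order
pruning: at a node with daughter values `x_i, x_j` and branch-adjusted
variances `v_i, v_j`, the raw contrast is `x_i − x_j` with expected
variance `v_i + v_j`; the nodal value is the inverse-variance weighted
mean and the node's branch is lengthened by `v_i v_j / (v_i + v_j)`. The
recursion also yields the GLS phylogenetic mean at the root and the
root's adjusted variance. Polytomies are rejected by default; an option
resolves them arbitrarily with zero-length branches, which leaves all GLS
quantities unchanged.

`regress_contrasts()` fits `y` contrasts on `x` contrasts by least
squares. The default is the through-origin fit that contrast theory
prescribes (contrast signs are arbitrary, and the fit is sign-invariant),
with residual d.f. `m − 1` for `m` contrasts. An `intercept_mode` fits an
intercept after positivising the contrasts on `x`; with 19 taxa this
reproduces the `1,16` degrees of freedom seen in analyses that fit an
intercept on contrasts, and both modes are labelled in the output. The F
statistic is the regression mean square over the residual mean square,
`p` is the upper tail of `F(1, df2)`, and the 95% CI half-width on the
exponent is `t₀.₉₇₅ · SE(b)`. The power-law elevation is back-transformed
from the two traits' phylogenetic root values, `a = 10^(ŷ₀ − b x̂₀)`; the
choice of root values as the anchoring point is the package's own, made
because they are the GLS estimates of the ancestral trait means.
Multiple regressions are reported without multiplicity correction, with a
note column recording how many tests were run. An excluded-taxon rerun
(for outliers such as a species with an extreme head volume) prunes the
tip — its sister absorbing the parent branch — and appends flagged rows.

## Ancestral states under Brownian motion

`asr_bm()` treats the (log₁₀) trait as evolving by BM with rate σ². The
rate is estimated by REML as the mean squared standardized contrast
(denominator `n − 1`). Each internal node's state estimate is the GLS
mean of the tree re-rooted at that node, computed in linear time by the
upward pruning pass plus a downward message pass; its variance is σ²
times the adjusted root variance of the re-rooted tree. The root estimate
is the global phylogenetic mean; tips carry their observations with zero
variance. The test suite checks every node estimate and variance against
a direct GLS solve with the full path-length covariance matrix and
against an independent implementation. Reconstruction operates on one
fixed input tree: the package deliberately does not integrate over tree
uncertainty (no MCMC), which is the main methodological difference from
joint Bayesian reconstructions, and results are reported on the log scale
with a point back-transform (`10^mean`) in the annotated NEXUS output.
Coverage is the default reconstruction trait because mean sensillum size
covaries strongly with density, making coverage the more interpretable
summary of sensory investment.

## Synthetic ground truth

The generators define the conditions under which the pipeline is tested:

* **Scenes** (`sim_scene()`): hard-core (non-overlapping) discs placed by
  sequential-inhibition dart throwing at intensity λ (default 20 mm⁻²,
  mid-range for the group under study) with fixed or lognormal radii
  (default 30 µm, a typical sensillum radius), inside a rectangular or
  elliptic roi (default 2 × 5 mm ≈ a postocular scale patch) at 5 µm
  pixels. The placed count is `round(λ × roi area)`. Centres are uniform
  in the roi and discs near the boundary may overhang it; this keeps the
  point process stationary inside the roi, so cell-count estimators are
  unbiased, at the cost of a little rendered area outside the roi.
  Packing is capped at a 0.4 area fraction to avoid rejection stalls. A
  pixel belongs to a disc when its centre lies within the radius — no
  anti-aliasing — and all census truth (count, area, coverage) is
  measured on the rendered raster, so estimator checks carry no
  discretization bias. Scenes are hard-core and stationary by
  construction; this is an assumption of the generator, not a claim about
  the spatial statistics of real sensilla, and clustered or gradient
  fields are out of scope.
* **Trees** (`sim_yule()`): the standard pure-birth construction —
  exponential waiting times at rate (lineages × birth rate), uniform
  choice of the splitting lineage, a final wait before the present — so
  trees are ultrametric like a time-calibrated phylogeny.
* **Traits** (`sim_bm()`, `sim_allometric_traits()`): BM forward
  simulation retaining true internal states; allometric pairs are built
  as `y = elevation + b·x + e` with `x` and `e` independent BM traits, so
  contrast regression of `y` on `x` has true exponent `b`.

Everything is a pure function of configuration plus seed (the RNG state
is restored afterwards), which is what makes the pipeline's end-to-end
determinism testable.

What passing the synthetic suites shows: the estimators are consistent
(mean density and coverage within Monte-Carlo error of census truth at
the default study conditions), the counting frame never double-counts,
the contrast algebra is exact against matrix GLS, slope recovery at the
effect size of interest (b = −1.04) is unbiased on 50-tip trees, and the
contrast F test holds its nominal 5% size under the BM null. What it does
not show: robustness to mis-segmented or merged sensilla labels, to roi
mis-specification, to non-BM trait evolution, or to spatially clustered
organs — real images and traits can violate all of these.

## Numerical choices and degenerate inputs

* Connected components are 8-connected; anti-aliased or diagonally
  touching disc pixels stay one organ.
* `N_s = 0` in a sample is not an error: density and coverage are 0 and
  mean size is missing.
* Cherries with two zero-length branches are rejected (zero pooled
  contrast variance); zero-length resolution of polytomies is safe
  everywhere else.
* A y-contrast vector that is identically zero yields slope 0, F = 0,
  p = 1, r² = 0 rather than 0/0.
* Regressions require at least 3 contrasts; x contrasts of zero variance
  are an error.
* Inverse-variance combinations treat a zero-variance component as exact,
  so observed tips dominate any message they enter.
* Species-to-tip matching is exact and case-sensitive; declared synonym
  maps (e.g. a congener substituted for DNA availability) are applied
  explicitly, and mismatches are reported in both directions.

## Problem sizes used in the test and acceptance suites

Scenes are simulated at 10 mm² (consistency checks, 200 replicates) and
2 mm² (conservation sweeps, 50 replicates); slope recovery uses 200
datasets on 50-tip trees; GLS oracle comparisons use 100 trees of 4–8
tips; the F-test size check uses 10⁴ twelve-tip trees. These sizes give
Monte-Carlo standard errors comfortably below the tolerances being
asserted while keeping a full run in the order of a minute or two.

## Known limitations

Sensilla must arrive pre-segmented as labels — the package does not
segment photographs. The head-volume proxy is a box product, not a true
volume. The ancestral reconstruction assumes BM on a single fixed tree;
directional or Ornstein-Uhlenbeck alternatives and tree uncertainty are
out of scope. The sem of a single-specimen species is undefined, and
downstream comparative analyses use species means only, so intraspecific
variance is not propagated into the regressions.
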