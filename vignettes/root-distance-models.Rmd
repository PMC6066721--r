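---
title: "Root distance models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root distance models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizodist)
```

## The soil perspective

Classical root system analysis describes the plant: root length density,
branching, diameters. `rhizodist` takes the complementary soil perspective:
for every soil voxel of a segmented 3D image it computes the Euclidean
distance to the nearest root voxel and summarizes the whole column by the
root distance histogram (RDH), the volume-fraction distribution of those
distances. This answers directly how well a root system has explored its
soil, and integrating the RDH up to a process-specific extent (water
uptake: several mm; rhizodeposits or poorly mobile nutrients: well under a
mm) yields the rhizosphere volume fraction for that process.

## The mixed triangular-gamma model

A single vertical (tap) root placed off-center in a cylindrical column
produces a roughly triangular distance density: the amount of soil at
radial distance $d$ from a line grows linearly in $d$ until the wall
interferes, and the asymmetric root position smears the cutoff into a
linear tail. With $p$ the root-to-wall distance,

$$f^{\Delta}_p(d) = \begin{cases} d/p^2 & 0 \le d \le p \\ (2p-d)/p^2 & p <
d \le 2p \\ 0 & d > 2p. \end{cases}$$

A developed network of laterals mixes many local distance scales and the
RDH moves to a gamma density with shape $k$ and scale $\theta$ (mean
$k\theta$, variance $k\theta^2$); $k = 1$ is the exponential limit, large
$k$ approaches a Gaussian. Intermediate growth stages are described by the
convex combination

$$f_{c,k,\theta,p}(d) = c\, f^{\Gamma}_{k,\theta}(d) + (1-c)\,
f^{\Delta}_p(d), \qquad c \in [0,1].$$

All four parameters have geometric meaning: $c$ tracks the development of
laterals, $\theta$ the tightness of soil exploration, $k$ the balance
between minimal and most frequent distances (stable near 2 for a
tap-rooted architecture with evenly spaced first-order laterals), $p$ the
tap-root-to-wall distance. At the boundaries the unused component's
parameters are non-identifiable; fits carry reliability flags (gamma
parameters uncertain when $c < 0.15$, triangular $p$ uncertain when
$c > 0.85$) rather than suppressing values.

### Units

Internal length unit is millimetres throughout (voxel sizes are sub-mm);
root length density $R_L$ is accepted in cm/cm³ and the half-mean distance
$HMD = (\pi R_L)^{-1/2}$ is returned in cm, matching how these quantities
are conventionally reported. `mmToCm()`/`cmToMm()` centralize conversions.

## Distance transform and histogram conventions

* Distances are voxel-center to voxel-center, from the exact separable
  Euclidean distance transform (parabola-envelope algorithm, Rcpp), which
  honors anisotropic spacing exactly; the suite verifies agreement with an
  exhaustive all-pairs search to $10^{-9}$ mm. There is no sub-voxel
  surface interpolation, so a soil voxel touching a root is one voxel
  spacing away, never 0, and the first histogram bin $[0, h)$ is
  structurally empty on voxel data.
* The distance map is computed on the **full grid** and masked to the
  region of interest afterwards, so roots outside a thin depth slab still
  attract distances. Depth profiles (default 5 mm slabs) would otherwise be
  biased, since slabs are thin relative to typical distances.
* Bins are uniform, half-open $[l, r)$ with the last bin closed; the
  default width is the voxel edge length — the natural resolution scale.
  Slab depth intervals are half-open $(z_0, z_1]$ so stacked slabs
  partition the column exactly.
* A slab with no soil voxels yields an explicitly empty histogram, not an
  error; a volume without root voxels raises an error, because a distance
  map is undefined rather than empty.
* `rhizosphereFraction()` interpolates linearly inside the bin straddling
  the requested extent — sub-bin resolution without assuming a density
  model. Note that with center-to-center distances an extent equal to one
  voxel size is the smallest meaningful one; below it the fraction is 0 by
  convention.
* The root surface density estimate extrapolates the per-width frequency
  of the first two nonempty bins linearly back to zero shell distance.
  The naive first-shell value $f_1/h$ systematically overestimates thin
  root surfaces because the first distance class lies one voxel outside
  the actual surface (shell curvature); the extrapolation removes most of
  that bias (measured residual error within about 15% for roots a few
  voxels thick, with doubling additivity preserved).

## Fitting

The fit criterion is deliberately statistical rather than visual: bin
probabilities are CDF differences of the mixture, renormalized
over the observed support, and the histogram counts enter a multinomial
log-likelihood (probabilities floored at $10^{-12}$: the finite triangular
support can zero out tail bins). At least 5 nonempty bins are required for
the four-parameter model.

Optimization runs BFGS on transformed parameters — logit $c$, log $k$,
log $\theta$, log $p$. The transform enforces the bounds and, more
importantly, conditions the problem: on the raw scale, where $c$ lives on
$[0,1]$ next to length parameters of tens of mm, bounded quasi-Newton runs
stalled in local optima far worse than the generating parameters. The
starts form a fixed deterministic grid: $c \in \{0.1, 0.5, 0.9\}$, $k = 2$
(the characteristic tap-rooted value), $\theta$ = sample mean / 2, and $p$
in {histogram mode, sample mean, 90th percentile} — the percentile start
matters because $p$ is a long-distance feature that mode and mean both
underestimate when the gamma component dominates the bulk. Multi-start
makes the known $c$-vs-component-parameter correlation harmless without
randomness: refitting a histogram is bit-reproducible. Parameter recovery
is verified in the suite: over seeded replicates of $10^5$ draws, median
$|\hat c - c| \le 0.05$ and median relative $\theta$ error $\le 10\%$ for
$c \in [0.3, 0.8]$.

## What the synthetic generator emulates — and what it does not

The generator rasterizes a vertical tap root (default radius 1.5 mm,
placed 10 mm off-axis, as commonly observed in pot experiments) with
whorls of straight first-order laterals (default: every 5 mm along the tap
root, 5 per whorl, final length 40 mm, 20° below horizontal, radius
0.6 mm, evenly spaced azimuths with a seeded random phase per whorl)
inside the standard column geometry (250 mm × Ø70 mm; volume-level tests
and examples use a 100 mm column — 200 × 140 × 140 voxels at 0.5 mm —
which exercises every code path at a fraction of the cost). These
densities were chosen to match a developed faba-bean-like architecture,
whose final-stage RDH has a mean of a few mm; with them the tap-only
volume fits $c \approx 0.01$ and the developed one $c \approx 0.90$, and
the growth series below reproduces the canonical trends.

Ground-truth root length density comes from the analytic clipped
centerline lengths, never from voxel counts, so $HMD$ comparisons are not
contaminated by rasterization error. Growth series use a timeline of
nondecreasing tap depths plus per-step lateral elongation; whorls activate
when the tap passes them, so root sets are nested and the series is a
perfectly registered input for root-age analysis. The canonical timeline
(tap at 75/90/90/90 mm, lateral growth 0/8/12/15 mm per step) mimics a
first scan with a deep tap root and no visible laterals, followed by
progressive lateral development; it yields a monotone increasing $c$ and a
monotone decreasing mean distance.

Deliberate simplifications: laterals are straight (no tropisms or soil
feedback), second-order laterals are absent (also largely absent in the
motivating experiments), whorls are perfectly periodic and azimuthally
even. The last point has a visible consequence: a *fully* developed
default system is more evenly distributed than a random pattern, so its
$\langle RDH \rangle / HMD$ ratio (0.885 in the worked example) falls
slightly below the random-pattern value, whereas developing stages — and
real, imperfect root systems — cluster and score well above it (0.97 at
half-grown laterals). Passing ordering tests on developing stages
therefore says nothing about segmentation noise, root surface roughness,
or curved roots in real data.

## Point patterns and the 69% / 89% reference ratios

For parallel roots the 3D problem reduces to 2D point patterns.
`hexagonalPattern()` offers two constructions:

* a triangular lattice clipped to a rectangular window, probed (after
  shrinking the probe window by one lattice spacing) for pure interior
  statistics — the mean nearest-distance is 66.9% of $HMD$, which is the
  closed-form value of the Voronoi-cell integral;
* the default bounded-bundle form: a complete $k$-ring hexagonal patch
  ($N = 1 + 3k(k+1)$ roots, default 127) centered in a **disc** cross
  section whose area is exactly $N/\rho$, so the bundle's density matches
  the nominal one by construction. Probing the full disc includes the
  soil between the bundle's hexagonal hull and the circular wall; this
  bounded-sample statistic is ~69% of $HMD$ and is invariant to the
  lattice spacing.

`poissonPattern()` fixes the point count to round(density × area)
(binomial rather than Poisson) so the density entering $HMD$ is exact;
probed on the full window, ten seeded realizations average ~89-90% of
$HMD$, a little above the unbounded-Poisson closed form $\sqrt{\pi}/2
\approx 88.6\%$ because bounded windows add edge distances. Probe points
are Monte Carlo (default $10^5$; error scales as $n^{-1/2}$), not pixel
rasterization, to avoid raster bias at edges.

## Degenerate inputs and numerical tolerances

* Histogram normalization is enforced to $10^{-9}$; density integrals to
  $10^{-6}$ in tests.
* Empty young-root sets (a time step that adds no voxels) raise an error,
  as the distance map to an empty set is undefined.
* A voxel leaving the root class in a later registered step keeps its
  earliest age and triggers a warning — these are registration artifacts,
  not biology.
* Root segments leaving the column are clipped with a warning; clipped
  length is also removed from the analytic ground truth.
* TIFF label volumes must contain only {0, 1, 2}; the voxel size is never
  read from TIFF tags (export conventions vary too much) and must be given
  explicitly.

## Known limitations

Root distance models cannot see branching angles, lateral ordering or
segment length distributions; they complement, not replace, skeleton-based
analysis. The surface-density estimator retains a voxel-roughness bias.
The generator's regularity (above) makes it a geometry oracle, not a
stand-in for biological variability: effect sizes measured on it transfer
to real CT data only qualitatively.
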