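# rhizodist

Quantifies root growth patterns from the **soil perspective**: instead of
describing a root system by its own traits (length density, branching), it
asks how far every bit of soil is from the nearest root, and how that
distribution evolves as the root system develops.

The package is aimed at researchers analysing segmented 3D root images from
X-ray CT (or MRI) time series of plants growing in cylindrical soil columns,
and at modellers who need compact descriptors of soil exploration.

## The model

For a segmented volume (labels: outside / soil / root), the exact Euclidean
distance transform assigns every soil voxel its distance *d* (mm) to the
nearest root voxel. The relative frequency distribution of these distances
over all soil voxels is the **root distance histogram (RDH)**: the relative
frequency of a distance class is the volume fraction of soil at that
distance from the root system.

Two architectural extremes shape the RDH:

* a single vertical tap root at distance *p* from the column wall gives a
  triangular density

  f<sup>Δ</sup><sub>p</sub>(d) = d/p² for 0 ≤ d ≤ p, (2p−d)/p² for
  p < d ≤ 2p, 0 beyond 2p;

* a developed network of laterals gives a gamma density

  f<sup>Γ</sup><sub>k,θ</sub>(d) = d^(k−1) e^(−d/θ) / (θ^k Γ(k)),

  with dimensionless shape *k* (≈ 2 for faba-bean-like architectures) and
  scale θ (mm), mean *k·θ* and variance *k·θ²*.

The **mixed triangular-gamma model** interpolates between them with a
weight *c* ∈ [0, 1]:

f<sub>c,k,θ,p</sub>(d) = c·f<sup>Γ</sup><sub>k,θ</sub>(d) +
(1−c)·f<sup>Δ</sup><sub>p</sub>(d).

`fitMixed()` estimates (c, k, θ, p) from a histogram by binned multinomial
maximum likelihood with a deterministic multi-start. When *c* < 0.15 the
gamma parameters are flagged unreliable, when *c* > 0.85 the triangular
parameter is (imbalanced mixing).

Derived metrics link the two perspectives:

* `hmd(R_L)` = (π·R_L)^(−1/2), the theoretical half-mean distance between
  equidistant parallel roots at root length density R_L (cm/cm³);
* `meanRdh()` = Σ fᵢ·dᵢ, the mean root-soil distance ⟨RDH⟩;
* `rhizosphereFraction(rdh, extent)`, the soil volume fraction within a
  process-specific distance of roots (the RDH's CDF);
* `rdhHmdRatio()`, the dimensionless ⟨RDH⟩/HMD: ≈ 0.69 for a hexagonal
  bundle of parallel roots, ≈ 0.89 for random root positions, and larger
  for clustered, continuous 3D networks.

Built-in generators make every analysis testable without CT data:
voxelized tap-root + lateral systems in a cylindrical column (static or as
a registered, nested growth series, with analytically exact ground-truth
root length density) and 2D hexagonal / random root point patterns.

## Worked example

Simulate a fully developed synthetic root system in a 100 mm × Ø70 mm
column at 0.5 mm voxels, compute its RDH and fit the mixed model:

```r
library(rhizodist)

spec <- rootSystemSpec(columnHeight = 100, columnRadius = 35,
                       taprootXY = c(45, 35), taprootDepth = 90)
sys <- rasterizeRootSystem(spec, voxelSize = 0.5)
roi <- roiMask("cylinder", centerXY = c(35, 35), radius = 35,
               zRange = c(0, 100))
rdh <- computeRdh(distanceMap(sys$volume), roi, binWidth = 0.5)
fitMixed(rdh)
#> FitResult (mixed triangular-gamma, binned ML)
#>   MixedModelParams: c = 0.8983  k = 2.418  theta = 2.305 mm  p = 4.925 mm
#>   logLik = -9.759e+06  converged = TRUE  n = 3.04352e+06
#>   uncertain parameters: p
```

The weight c = 0.90 says the RDH is gamma-dominated, as expected for a
developed lateral network (and *p* is flagged accordingly); k ≈ 2.4 is the
characteristic faba-bean shape; θ ≈ 2.3 mm measures how tightly the
laterals have explored the soil.

```r
meanRdh(rdh)                             # 5.50 mm mean root-soil distance
hmd(sys$R_L_cm_per_cm3)                  # 0.621 cm for R_L = 0.825 cm/cm3
rdhHmdRatio(rdh, sys$R_L_cm_per_cm3)     # 0.885
rhizosphereFraction(rdh, 5)              # 0.521: half the soil within 5 mm
```

Point-pattern reference values:

```r
patternDistanceStats(hexagonalPattern(0.01), seed = 1)$ratio  # ~0.69
patternDistanceStats(poissonPattern(0.01, seed = 1))$ratio    # ~0.89-0.91
```

A command-line front end over the same functions lives in
`inst/scripts/rhizodist.R` with verbs `simulate`, `rdh`, `fit`, `profile`,
`rhizo` and `pattern` (multi-page TIFF volumes in, CSV/JSON out).

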