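test_that("rasterized root volume matches analytic cylinder volume", {
  # tap root only, voxel = radius / 3
  spec <- miniSpec()
  sys <- suppressWarnings(rasterizeRootSystem(spec, 0.4, lateralLength = 0))
  nRoot <- sum(sys$volume@voxels == 2L)
  voxVol <- nRoot * 0.4^3
  analytic <- pi * spec@taprootRadius^2 * spec@taprootDepth
  expect_lt(abs(voxVol / analytic - 1), 0.15)
  # ground truth length is the clipped centerline, not voxel-derived
  expect_equal(sys$totalLength_mm, spec@taprootDepth)
  colVol <- pi * spec@columnRadius^2 * spec@columnHeight
  expect_equal(sys$R_L_cm_per_cm3, 100 * spec@taprootDepth / colVol)
})

test_that("generator is deterministic and warns when roots are clipped", {
  s1 <- suppressWarnings(rasterizeRootSystem(miniSpec(), 0.5))
  s2 <- suppressWarnings(rasterizeRootSystem(miniSpec(), 0.5))
  expect_identical(s1$volume@voxels, s2$volume@voxels)
  expect_identical(s1$R_L_cm_per_cm3, s2$R_L_cm_per_cm3)
  # different azimuth seed changes the volume
  s3 <- suppressWarnings(rasterizeRootSystem(miniSpec(seed = 99L), 0.5))
  expect_false(identical(s1$volume@voxels, s3$volume@voxels))
  # laterals longer than the column radius must be clipped
  expect_warning(rasterizeRootSystem(miniSpec(lateralLength = 30), 0.5),
                 "clipped")
  expect_error(rasterizeRootSystem(miniSpec(), 2), "voxelSize")
})

test_that("tap-only and developed systems produce the expected RDH shapes", {
  tap <- suppressWarnings(rasterizeRootSystem(miniSpec(), 0.5,
                                              lateralLength = 0))
  rdhTap <- computeRdh(distanceMap(tap$volume), miniRoi(), 0.5)
  # triangular: rising then falling, mean near the root-wall distance p = 7
  fTap <- fitMixed(rdhTap)
  expect_lt(mixingWeight(modelParams(fTap)), 0.15)

  dev <- suppressWarnings(rasterizeRootSystem(miniSpec(lateralLength = 9,
                                                       lateralSpacing = 4), 0.5))
  fDev <- fitMixed(computeRdh(distanceMap(dev$volume), miniRoi(), 0.5))
  expect_gt(mixingWeight(modelParams(fDev)),
            mixingWeight(modelParams(fTap)))
})

test_that("growth series are nested, registered and age-consistent", {
  spec <- miniSpec()
  tl <- growthTimeline(tapDepth = c(15, 24, 27, 27),
                       lateralGrowth = c(0, 4, 4, 4))
  ser <- suppressWarnings(growTimeSeries(spec, tl, 0.5))
  expect_length(ser, 4)
  for (t in 2:4) {
    prev <- ser[[t - 1]]@voxels == 2L
    cur <- ser[[t]]@voxels == 2L
    expect_true(all(cur[prev]))          # root sets nested over time
    expect_identical(dim(ser[[t]]@voxels), dim(ser[[1]]@voxels))
  }
  # age volume agrees with direct bookkeeping over the series
  age <- buildAgeVolume(ser)
  firstSeen <- array(0L, dim(ser[[1]]@voxels))
  for (t in rev(seq_along(ser)))
    firstSeen[ser[[t]]@voxels == 2L] <- t
  expect_identical(age@ages, firstSeen)

  # no-growth step: consecutive identical volumes
  expect_identical(ser[[3]]@voxels == 2L & ser[[4]]@voxels == 2L,
                   ser[[4]]@voxels == 2L)
  tl0 <- growthTimeline(tapDepth = c(27, 27), lateralGrowth = c(0, 0))
  ser0 <- suppressWarnings(growTimeSeries(spec, tl0, 0.5))
  expect_identical(ser0[[1]]@voxels, ser0[[2]]@voxels)

  # later histograms have smaller means (soil better explored)
  means <- vapply(ser, function(v)
    meanRdh(computeRdh(distanceMap(v), miniRoi(), 0.5)), numeric(1))
  expect_true(all(diff(means) <= 1e-9))

  expect_error(growthTimeline(c(10, 5), 1), "nondecreasing")
})

test_that("hexagonal patterns are equidistant lattices at the set density", {
  rho <- 0.01
  pat <- hexagonalPattern(rho, window = c(200, 200))
  pts <- patternPoints(pat)
  expect_gt(nrow(pts), 0.85 * rho * 200 * 200)
  expect_lt(nrow(pts), 1.15 * rho * 200 * 200)

  s <- sqrt(2 / (sqrt(3) * rho))
  # interior points have 6 nearest neighbors at the lattice spacing
  ctr <- which(pts[, 1] > 2 * s & pts[, 1] < 200 - 2 * s &
               pts[, 2] > 2 * s & pts[, 2] < 200 - 2 * s)
  for (i in ctr[1:5]) {
    dd <- sort(sqrt(colSums((t(pts) - pts[i, ])^2)))[2:7]
    expect_equal(dd, rep(s, 6), tolerance = 1e-9)
  }
  # every window point is within the lattice circumradius of a point
  set.seed(5)
  px <- runif(2000, s, 200 - s); py <- runif(2000, s, 200 - s)
  nd <- vapply(seq_along(px), function(i)
    min(sqrt((pts[, 1] - px[i])^2 + (pts[, 2] - py[i])^2)), numeric(1))
  expect_lte(max(nd), s / sqrt(3) + 1e-9)

  expect_error(hexagonalPattern(1e-5, window = c(20, 20)), "fewer than 7")
})

test_that("random patterns are reproducible with the right intensity", {
  p1 <- poissonPattern(0.01, c(150, 150), seed = 3)
  p2 <- poissonPattern(0.01, c(150, 150), seed = 3)
  expect_identical(patternPoints(p1), patternPoints(p2))
  expect_equal(nrow(patternPoints(p1)), round(0.01 * 150 * 150))
  expect_equal(p1@density, nrow(patternPoints(p1)) / 150^2)

  # mean nearest-neighbor distance of a Poisson pattern is 1/(2 sqrt(rho))
  nnMeans <- vapply(1:8, function(s) {
    pp <- patternPoints(poissonPattern(0.02, c(120, 120), seed = s))
    d <- vapply(seq_len(nrow(pp)), function(i) {
      dd <- sqrt((pp[, 1] - pp[i, 1])^2 + (pp[, 2] - pp[i, 2])^2)
      min(dd[-i])
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_equal(mean(nnMeans), 1 / (2 * sqrt(0.02)), tolerance = 0.05)
})

test_that("disc bundles are complete hexagonal patches at exact density", {
  rho <- 0.01
  for (k in c(3L, 6L)) {
    pat <- hexagonalPattern(rho, rings = k)
    n <- nrow(patternPoints(pat))
    expect_equal(n, 1 + 3 * k * (k + 1))       # centered hexagonal number
    # disc area matches N / rho exactly, so density is exact by construction
    expect_equal(pi * pat@window^2, n / rho)
    # the hexagonal patch is not disc-shaped: its corner roots may protrude
    # a few percent beyond the area-matched cross section
    expect_true(all(sqrt(rowSums(patternPoints(pat)^2)) <=
                      1.05 * pat@window))
  }
})

test_that("pattern distance statistics reproduce the clustering ordering", {
  rho <- 0.01
  hex <- patternDistanceStats(hexagonalPattern(rho), nProbe = 5e4, seed = 2)
  ran <- patternDistanceStats(poissonPattern(rho, c(200, 200), seed = 7),
                              nProbe = 5e4, seed = 2)
  expect_lt(hex$ratio, ran$ratio)        # lattice explores soil best
  expect_equal(hex$hmd, (pi * rho)^(-0.5))

  # ratios do not depend on the actual spacing between roots
  hex4 <- patternDistanceStats(hexagonalPattern(4 * rho), nProbe = 5e4,
                               seed = 2)
  expect_equal(hex4$ratio, hex$ratio, tolerance = 0.02)
  # interior (rectangular, shrunk-window) statistics give the pure lattice
  # value, below the bounded-bundle one
  hexInt <- patternDistanceStats(hexagonalPattern(rho, c(200, 200)),
                                 nProbe = 5e4, seed = 2)
  expect_equal(hexInt$ratio, 0.6686, tolerance = 0.01)

  # degenerate: one point far from covering a window at the nominal density
  # gives an edge-dominated ratio far above 1
  lone <- new("PointPattern2D", points = matrix(c(100, 100), 1),
              window = c(200, 200), windowShape = "rect", density = rho,
              kind = "random")
  expect_gt(patternDistanceStats(lone, nProbe = 1e4, seed = 1)$ratio, 1)
  none <- new("PointPattern2D", points = matrix(numeric(), 0, 2),
              window = c(10, 10), windowShape = "rect", density = 1,
              kind = "random")
  expect_error(patternDistanceStats(none), "degenerate")
})
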