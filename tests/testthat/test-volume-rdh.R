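test_that("distance map matches exact geometry for simple root sets", {
  # single root voxel at the center of a 3x3x3 isotropic grid
  a <- array(1L, c(3, 3, 3)); a[2, 2, 2] <- 2L
  dm <- distanceMap(segmentedVolume(a, 1))
  expect_equal(dm@distances[1, 2, 2], 1)
  expect_equal(dm@distances[2, 1, 2], 1)
  expect_equal(dm@distances[1, 1, 2], sqrt(2))
  expect_equal(dm@distances[1, 1, 1], sqrt(3))
  expect_true(is.na(dm@distances[2, 2, 2]))

  # root plane at the top: distance grows linearly with depth index
  b <- array(1L, c(6, 4, 4)); b[1, , ] <- 2L
  dmb <- distanceMap(segmentedVolume(b, c(0.5, 1, 1)))
  for (z in 2:6)
    expect_equal(unique(as.vector(dmb@distances[z, , ])), (z - 1) * 0.5)

  expect_error(distanceMap(segmentedVolume(array(1L, c(3, 3, 3)), 1)),
               "no root voxels")
})

test_that("distance map equals the exhaustive search oracle", {
  for (s in 1:4) {
    dims <- c(sample(6:14, 1), sample(6:14, 1), sample(6:14, 1))
    sp <- c(0.6, 1.0, 1.3)  # anisotropic
    vol <- randomVolume(dims, pRoot = 0.05, spacing = sp, seed = 100 + s)
    dm <- distanceMap(vol)
    brute <- bruteForceDistances(vol)
    expect_lt(max(abs(dm@distances - brute), na.rm = TRUE), 1e-9)
  }
})

test_that("adding root voxels never increases any distance", {
  vol <- randomVolume(c(12, 10, 11), pRoot = 0.02, seed = 7)
  d1 <- distanceMap(vol)@distances
  v2 <- vol@voxels
  set.seed(8)
  v2[sample(which(v2 == 1L), 20)] <- 2L
  d2 <- distanceMap(segmentedVolume(v2, vol@spacing))@distances
  both <- !is.na(d1) & !is.na(d2)
  expect_true(all(d2[both] <= d1[both] + 1e-12))
})

test_that("RDH is normalized, respects the ROI and refines consistently", {
  sys <- suppressWarnings(rasterizeRootSystem(miniSpec(), 0.5))
  dm <- distanceMap(sys$volume)
  rdh <- computeRdh(dm, miniRoi(), binWidth = 0.5)
  expect_equal(sum(relFreq(rdh)), 1, tolerance = 1e-12)
  expect_true(all(relFreq(rdh) >= 0))
  expect_gt(nVoxels(rdh), 0)

  # halving the bin width leaves cumulative sums at shared edges unchanged
  fine <- computeRdh(dm, miniRoi(), binWidth = 0.25)
  cumCoarse <- cumsum(relFreq(rdh))
  cumFine <- cumsum(relFreq(fine))
  shared <- match(binBreaks(rdh)[-1], binBreaks(fine)[-1])
  shared <- shared[!is.na(shared)]
  expect_equal(cumFine[shared], cumCoarse[seq_along(shared)],
               tolerance = 1e-9)

  # all soil at one distance: root plane above a single soil plane
  b <- array(0L, c(2, 3, 3)); b[1, , ] <- 2L; b[2, , ] <- 1L
  rdh1 <- computeRdh(distanceMap(segmentedVolume(b, 1)), binWidth = 1)
  expect_equal(sum(relFreq(rdh1) > 0), 1)
  expect_equal(max(relFreq(rdh1)), 1)

  # empty ROI errors
  emptyRoi <- roiMask("cylinder", centerXY = c(5, 5), radius = 2,
                      zRange = c(28, 30))
  v <- sys$volume@voxels
  v[55:60, , ] <- 0L
  expect_error(computeRdh(distanceMap(segmentedVolume(v, 0.5)), emptyRoi),
               "no soil")
})

test_that("slab histograms partition the global histogram", {
  sys <- suppressWarnings(rasterizeRootSystem(miniSpec(), 0.5))
  dm <- distanceMap(sys$volume)
  glob <- computeRdh(dm, miniRoi(), binWidth = 0.5)
  slabs <- slabRdhs(dm, miniRoi(), slabThickness = 5, binWidth = 0.5)
  expect_length(slabs, 6)

  # counts per bin, summed over slabs, reproduce the global counts
  nb <- length(glob@counts)
  acc <- numeric(nb)
  for (s in slabs) {
    if (isEmptyHistogram(s$rdh)) next
    cnt <- s$rdh@counts
    acc[seq_along(cnt)] <- acc[seq_along(cnt)] + cnt
  }
  expect_equal(acc, glob@counts)
  expect_equal(sum(vapply(slabs, function(s) nVoxels(s$rdh), numeric(1))),
               nVoxels(glob))

  # one full-height slab reproduces the global histogram
  one <- slabRdhs(dm, miniRoi(), slabThickness = 30, binWidth = 0.5)
  expect_length(one, 1)
  expect_equal(one[[1]]$rdh@counts, glob@counts)

  # a slab outside the rooted region with no soil is flagged, not an error
  v <- sys$volume@voxels
  v[1:10, , ] <- 0L
  dm2 <- distanceMap(segmentedVolume(v, 0.5))
  slabs2 <- slabRdhs(dm2, miniRoi(), slabThickness = 5, binWidth = 0.5)
  expect_true(isEmptyHistogram(slabs2[[1]]$rdh))
  expect_false(isEmptyHistogram(slabs2[[3]]$rdh))
})

test_that("root age volumes record first appearance", {
  a1 <- array(1L, c(4, 3, 3))
  a2 <- a1; a2[2, 2, 2] <- 2L
  a3 <- a2; a3[3, 2, 2] <- 2L
  series <- lapply(list(a1, a2, a3), segmentedVolume, spacing = 1)
  age <- buildAgeVolume(series)
  expect_equal(age@ages[2, 2, 2], 2L)   # appeared at step 2
  expect_equal(age@ages[3, 2, 2], 3L)
  expect_equal(age@ages[1, 1, 1], 0L)   # never root
  expect_equal(age@nSteps, 3L)

  # single-volume series: ages are the root mask
  age1 <- buildAgeVolume(series[3])
  expect_true(all(age1@ages[series[[3]]@voxels == 2L] == 1L))
  expect_true(all(age1@ages[series[[3]]@voxels != 2L] == 0L))

  # voxel leaving the root class: warning, earliest age kept
  a4 <- a3; a4[2, 2, 2] <- 1L
  expect_warning(age2 <- buildAgeVolume(lapply(list(a1, a2, a4),
                                               segmentedVolume, spacing = 1)),
                 "earliest age")
  expect_equal(age2@ages[2, 2, 2], 2L)

  expect_error(buildAgeVolume(list(series[[1]],
                                   segmentedVolume(array(1L, c(3, 3, 3)), 1))),
               "shape")
})

test_that("young-root distance maps target only newly grown voxels", {
  a1 <- array(1L, c(5, 5, 5)); a1[1, 3, 3] <- 2L
  a2 <- a1; a2[4, 2, 2] <- 2L
  series <- lapply(list(a1, a2), segmentedVolume, spacing = 1)
  age <- buildAgeVolume(series)
  ydm <- youngRootDistanceMap(series, age, t = 2)
  # distances are to the single new voxel at (4, 2, 2)
  idx <- which(series[[2]]@voxels != 2L, arr.ind = TRUE)
  for (i in sample(nrow(idx), 20)) {
    v <- idx[i, ]
    expect_equal(ydm@distances[v[1], v[2], v[3]],
                 sqrt(sum((v - c(4, 2, 2))^2)))
  }
  # no growth at t: error
  expect_error(youngRootDistanceMap(list(series[[1]], series[[1]]),
                                    buildAgeVolume(list(series[[1]],
                                                        series[[1]])), 2),
               "no root voxels first appeared")

  # young-root rhizosphere fraction cannot exceed the full-network one
  full <- distanceMap(series[[2]])
  roi <- roiMask("full", zRange = c(0, 5))
  rdhFull <- computeRdh(full, roi, 1)
  rdhYoung <- computeRdh(ydm, roi, 1)
  for (ext in c(1, 2, 4))
    expect_lte(rhizosphereFraction(rdhYoung, ext),
               rhizosphereFraction(rdhFull, ext) + 1e-12)
})
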