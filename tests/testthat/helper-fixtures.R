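# Small, fast fixtures shared across test files. All volumes are generated
# in code; nothing is read from disk.

# 100 mm column, 35 mm radius: the depth-truncated study column used for
# volume-level checks (full 250 mm height is not needed to exercise any
# code path and would slow the suite down).
studySpec <- function(...) {
  defaults <- list(columnHeight = 100, columnRadius = 35,
                   taprootXY = c(45, 35), taprootDepth = 90,
                   taprootRadius = 1.5, lateralSpacing = 5,
                   lateralsPerWhorl = 5L, lateralAngle = 20,
                   lateralLength = 40, lateralRadius = 0.6, seed = 1L)
  do.call(rootSystemSpec, utils::modifyList(defaults, list(...)))
}

studyRoi <- function() {
  roiMask("cylinder", centerXY = c(35, 35), radius = 35, zRange = c(0, 100))
}

# canonical growth timeline: deep tap root first, laterals developing later
studyTimeline <- function() {
  growthTimeline(tapDepth = c(75, 90, 90, 90),
                 lateralGrowth = c(0, 8, 12, 15))
}

# tiny column for I/O and CLI tests
miniSpec <- function(...) {
  defaults <- list(columnHeight = 30, columnRadius = 10,
                   taprootXY = c(13, 10), taprootDepth = 27,
                   taprootRadius = 1.2, lateralSpacing = 6,
                   lateralsPerWhorl = 3L, lateralAngle = 20,
                   lateralLength = 8, lateralRadius = 0.8, seed = 1L)
  do.call(rootSystemSpec, utils::modifyList(defaults, list(...)))
}

miniRoi <- function() {
  roiMask("cylinder", centerXY = c(10, 10), radius = 10, zRange = c(0, 30))
}

# random labelled volume with guaranteed root and soil voxels
randomVolume <- function(dims, pRoot = 0.02, spacing = 1, seed = 1) {
  set.seed(seed)
  v <- array(1L, dims)
  n <- prod(dims)
  nRoot <- max(1L, round(pRoot * n))
  v[sample.int(n, nRoot)] <- 2L
  segmentedVolume(v, spacing)
}

# exhaustive nearest-root search: the independent distance-transform oracle
bruteForceDistances <- function(volume) {
  vox <- volume@voxels
  sp <- volume@spacing
  rootIdx <- which(vox == 2L, arr.ind = TRUE)
  out <- array(NA_real_, dim(vox))
  nonroot <- which(vox != 2L, arr.ind = TRUE)
  rt <- t(rootIdx) * sp  # 3 x nroot, scaled
  for (i in seq_len(nrow(nonroot))) {
    v <- nonroot[i, ] * sp
    out[nonroot[i, 1], nonroot[i, 2], nonroot[i, 3]] <-
      sqrt(min(colSums((rt - v)^2)))
  }
  out
}
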