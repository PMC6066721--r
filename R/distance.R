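#' Euclidean distance transform of a segmented volume
#'
#' Computes, for every non-root voxel, the exact Euclidean distance (mm,
#' voxel-center to voxel-center, honoring anisotropic spacing) to the nearest
#' root voxel, using a separable exact distance transform on the full grid.
#' Root voxels get NA (the distance is undefined there). Distances are
#' computed on the full grid; restriction to a region of interest happens at
#' histogram time, so roots outside a depth sub-range still attract
#' distances.
#'
#' @param volume a \linkS4class{SegmentedVolume} with at least one root
#'   voxel.
#' @return A \linkS4class{DistanceMap}.
#' @examples
#' a <- array(1L, c(3, 3, 3)); a[2, 2, 2] <- 2L
#' dm <- distanceMap(segmentedVolume(a, spacing = 1))
#' @export
distanceMap <- function(volume) {
  stopifnot(is(volume, "SegmentedVolume"))
  validObject(volume)
  root <- volume@voxels == 2L
  if (!any(root))
    stop("volume contains no root voxels; distance map is undefined",
         call. = FALSE)
  .edtFromMask(root, dim(volume@voxels), volume@spacing,
               soil = volume@voxels == 1L)
}

.edtFromMask <- function(rootMask, dims, spacing, soil) {
  d2 <- edt3d_sq(as.vector(rootMask), as.integer(dims),
                 as.numeric(spacing))
  d <- sqrt(d2)
  d[as.vector(rootMask)] <- NA_real_
  dim(d) <- dims
  new("DistanceMap", distances = d, soil = soil, spacing = spacing)
}

#' Root age volume from a registered time series
#'
#' Given registered segmented volumes ordered by time, records for each voxel
#' the first time step (1-based) at which it was classified as root; 0 where
#' it never was. A voxel that leaves the root class at a later step keeps its
#' earliest age and triggers a warning (registration artifacts).
#'
#' @param series list of \linkS4class{SegmentedVolume}, same grid and
#'   spacing, ordered by time.
#' @return A \linkS4class{RootAgeVolume}.
#' @export
buildAgeVolume <- function(series) {
  stopifnot(is.list(series), length(series) >= 1)
  lapply(series, function(v) stopifnot(is(v, "SegmentedVolume")))
  dims <- dim(series[[1]]@voxels)
  sp <- series[[1]]@spacing
  for (v in series[-1]) {
    if (!identical(dim(v@voxels), dims) || !identical(v@spacing, sp))
      stop("all volumes in the series must share grid shape and spacing",
           call. = FALSE)
  }
  ages <- array(0L, dims)
  shrank <- FALSE
  for (t in seq_along(series)) {
    root <- series[[t]]@voxels == 2L
    if (any(ages > 0L & ages < t & !root)) shrank <- TRUE
    newRoot <- root & ages == 0L
    ages[newRoot] <- as.integer(t)
  }
  if (shrank)
    warning("some voxels left the root class in a later step; ",
            "earliest age kept")
  new("RootAgeVolume", ages = ages, nSteps = length(series), spacing = sp)
}

#' Distance map to young roots only
#'
#' Distance transform where the target set is restricted to root voxels that
#' first appeared at time step \code{t} (i.e. grew since the previous scan).
#' Soil is every non-root voxel at time \code{t}, so the resulting histogram
#' is directly comparable to the full-network one.
#'
#' @param series list of registered \linkS4class{SegmentedVolume}.
#' @param age a \linkS4class{RootAgeVolume} built from the same series.
#' @param t time step index, >= 2.
#' @return A \linkS4class{DistanceMap} with distances to young roots.
#' @export
youngRootDistanceMap <- function(series, age, t) {
  stopifnot(is(age, "RootAgeVolume"), t >= 2, t <= age@nSteps)
  vol <- series[[t]]
  stopifnot(is(vol, "SegmentedVolume"))
  young <- age@ages == as.integer(t)
  if (!any(young))
    stop("no root voxels first appeared at step ", t,
         "; young-root distance map is undefined", call. = FALSE)
  .edtFromMask(young, dim(vol@voxels), vol@spacing,
               soil = vol@voxels == 1L)
}
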