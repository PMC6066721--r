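#' Logical voxel mask of a region of interest
#'
#' A voxel belongs to the ROI when its center (at (i - 0.5) * spacing for
#' 1-based index i along each axis) falls inside the cylinder and depth
#' range.
#'
#' @param roi a \linkS4class{RoiMask}.
#' @param dims grid dimensions (nz, ny, nx).
#' @param spacing voxel edge lengths (dz, dy, dx) in mm.
#' @return Logical 3D array.
#' @export
roiVoxelMask <- function(roi, dims, spacing) {
  stopifnot(is(roi, "RoiMask"))
  validObject(roi)
  zc <- (seq_len(dims[1]) - 0.5) * spacing[1]
  # half-open (top, bottom] so that stacked slabs partition the depth range
  inZ <- zc > roi@zRange[1] & zc <= roi@zRange[2]
  if (roi@shape == "full") {
    mask <- array(TRUE, dims)
    mask[!inZ, , ] <- FALSE
    return(mask)
  }
  yc <- (seq_len(dims[2]) - 0.5) * spacing[2]
  xc <- (seq_len(dims[3]) - 0.5) * spacing[3]
  r2 <- outer((yc - roi@centerXY[2])^2, (xc - roi@centerXY[1])^2, "+")
  inXY <- r2 <= roi@radius^2
  mask <- array(FALSE, dims)
  for (z in which(inZ)) mask[z, , ] <- inXY
  mask
}

#' Root distance histogram of a region of interest
#'
#' Bins the distances of all soil voxels inside the ROI into uniform bins of
#' width \code{binWidth} (half-open [left, right), last bin closed). The
#' relative frequency of a bin is the volume fraction of ROI soil at that
#' distance to the nearest root.
#'
#' @param dmap a \linkS4class{DistanceMap}.
#' @param roi a \linkS4class{RoiMask}; the distance map itself was computed
#'   on the full grid, so roots outside the ROI still attract distances.
#' @param binWidth bin width in mm; defaults to the voxel edge length
#'   (isotropic case: one natural resolution scale).
#' @return A \linkS4class{RootDistanceHistogram}.
#' @export
computeRdh <- function(dmap, roi = NULL, binWidth = NULL) {
  stopifnot(is(dmap, "DistanceMap"))
  if (is.null(binWidth)) binWidth <- dmap@spacing[1]
  stopifnot(binWidth > 0)
  sel <- dmap@soil
  if (!is.null(roi))
    sel <- sel & roiVoxelMask(roi, dim(dmap@distances), dmap@spacing)
  d <- dmap@distances[sel]
  d <- d[!is.na(d)]
  if (length(d) == 0)
    stop("the region of interest contains no soil voxels", call. = FALSE)
  rdhFromSamples(d, binWidth)
}

#' Build a root distance histogram from raw distances
#'
#' Shared binning used both for voxel distances and for model draws in
#' parameter-recovery studies.
#'
#' @param d numeric distances (mm), nonnegative.
#' @param binWidth bin width in mm.
#' @return A \linkS4class{RootDistanceHistogram}.
#' @export
rdhFromSamples <- function(d, binWidth) {
  stopifnot(length(d) >= 1, all(d >= 0), binWidth > 0)
  nb <- max(1L, as.integer(ceiling(max(d) / binWidth + 1e-12)))
  breaks <- seq(0, by = binWidth, length.out = nb + 1L)
  idx <- pmin(findInterval(d, breaks, left.open = FALSE), nb)
  counts <- tabulate(idx, nbins = nb)
  new("RootDistanceHistogram", breaks = breaks, counts = as.numeric(counts),
      relFreq = counts / length(d), nVoxels = as.numeric(length(d)),
      binWidth = binWidth)
}

.emptyRdh <- function(binWidth) {
  new("RootDistanceHistogram", breaks = c(0, binWidth), counts = 0,
      relFreq = 0, nVoxels = 0, binWidth = binWidth)
}

#' Depth-resolved root distance histograms
#'
#' Partitions the ROI depth range into equidistant slabs (top-down) and
#' builds one histogram per slab from the soil voxels whose centers fall in
#' the slab, using the global 3D distance map (roots above or below a slab
#' still count as nearest roots). Slabs without soil voxels yield an empty
#' histogram, not an error.
#'
#' @param dmap a \linkS4class{DistanceMap}.
#' @param roi a \linkS4class{RoiMask} giving the lateral extent and depth
#'   range.
#' @param slabThickness slab thickness in mm (5 mm in typical profiles).
#' @param binWidth histogram bin width in mm; default voxel edge length.
#' @return A list with one element per slab, each a list with elements
#'   \code{zRange} (depth interval, mm) and \code{rdh}
#'   (\linkS4class{RootDistanceHistogram}).
#' @export
slabRdhs <- function(dmap, roi, slabThickness = 5, binWidth = NULL) {
  stopifnot(is(dmap, "DistanceMap"), is(roi, "RoiMask"), slabThickness > 0)
  if (is.null(binWidth)) binWidth <- dmap@spacing[1]
  z0 <- roi@zRange[1]
  z1 <- roi@zRange[2]
  edges <- seq(z0, z1, by = slabThickness)
  if (edges[length(edges)] < z1) edges <- c(edges, z1)
  out <- vector("list", length(edges) - 1L)
  for (i in seq_along(out)) {
    slabRoi <- new("RoiMask", shape = roi@shape, centerXY = roi@centerXY,
                   radius = roi@radius, zRange = c(edges[i], edges[i + 1]))
    rdh <- tryCatch(computeRdh(dmap, slabRoi, binWidth),
                    error = function(e) .emptyRdh(binWidth))
    out[[i]] <- list(zRange = c(edges[i], edges[i + 1]), rdh = rdh)
  }
  out
}
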