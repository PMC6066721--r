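#' Construct mixed triangular-gamma model parameters
#'
#' @param c mixing weight of the gamma component, in [0, 1].
#' @param k gamma shape parameter (dimensionless), > 0.
#' @param theta gamma scale parameter in mm, > 0.
#' @param p tap-root-to-wall distance in mm, > 0.
#' @return A \linkS4class{MixedModelParams} object.
#' @examples
#' mixedModelParams(c = 0.7, k = 2, theta = 4, p = 20)
#' @export
mixedModelParams <- function(c, k, theta, p) {
  new("MixedModelParams", c = as.numeric(c), k = as.numeric(k),
      theta = as.numeric(theta), p = as.numeric(p))
}

#' Construct a segmented volume
#'
#' @param voxels 3D array of labels: 0 outside, 1 soil, 2 root. Axes (z, y,
#'   x), z = depth increasing downward.
#' @param spacing voxel edge lengths (dz, dy, dx) in mm; a single value is
#'   recycled (isotropic voxels).
#' @return A \linkS4class{SegmentedVolume}.
#' @export
segmentedVolume <- function(voxels, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  storage.mode(voxels) <- "integer"
  new("SegmentedVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a region-of-interest mask
#'
#' @param shape "cylinder" or "full".
#' @param centerXY cylinder axis (x, y) position in mm (cylinder only).
#' @param radius cylinder radius in mm (cylinder only).
#' @param zRange depth interval (top, bottom) in mm.
#' @return A \linkS4class{RoiMask}.
#' @export
roiMask <- function(shape = c("cylinder", "full"), centerXY = numeric(),
                    radius = numeric(), zRange) {
  shape <- match.arg(shape)
  new("RoiMask", shape = shape, centerXY = as.numeric(centerXY),
      radius = as.numeric(radius), zRange = as.numeric(zRange))
}

#' @describeIn mixedModelParams Mixing weight c accessor.
#' @param x object to access.
#' @export
setMethod("mixingWeight", "MixedModelParams", function(x) x@c)
#' @describeIn mixedModelParams Gamma shape k accessor.
#' @export
setMethod("gammaShape", "MixedModelParams", function(x) x@k)
#' @describeIn mixedModelParams Gamma scale theta (mm) accessor.
#' @export
setMethod("gammaScale", "MixedModelParams", function(x) x@theta)
#' @describeIn mixedModelParams Tap-root-to-wall distance p (mm) accessor.
#' @export
setMethod("wallDistance", "MixedModelParams", function(x) x@p)

#' @export
setMethod("voxelSpacing", "SegmentedVolume", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "DistanceMap", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "RootAgeVolume", function(x) x@spacing)

#' @export
setMethod("relFreq", "RootDistanceHistogram", function(x) x@relFreq)
#' @export
setMethod("binBreaks", "RootDistanceHistogram", function(x) x@breaks)
#' @export
setMethod("binMidpoints", "RootDistanceHistogram", function(x)
  (x@breaks[-length(x@breaks)] + x@breaks[-1]) / 2)
#' @export
setMethod("nVoxels", "RootDistanceHistogram", function(x) x@nVoxels)
#' @export
setMethod("nVoxels", "FitResult", function(x) x@nVoxels)

#' @export
setMethod("modelParams", "FitResult", function(x) x@params)
#' @export
setMethod("reliability", "FitResult", function(x) x@reliability)

#' @export
setMethod("patternPoints", "PointPattern2D", function(x) x@points)

setMethod("show", "MixedModelParams", function(object) {
  cat("MixedModelParams: c =", format(object@c, digits = 4),
      " k =", format(object@k, digits = 4),
      " theta =", format(object@theta, digits = 4), "mm",
      " p =", format(object@p, digits = 4), "mm\n")
})

setMethod("show", "SegmentedVolume", function(object) {
  d <- dim(object@voxels)
  tab <- tabulate(as.vector(object@voxels) + 1L, nbins = 3L)
  cat(sprintf("SegmentedVolume: %d x %d x %d voxels (z, y, x), %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  outside: %d  soil: %d  root: %d\n", tab[1], tab[2], tab[3]))
})

setMethod("show", "DistanceMap", function(object) {
  d <- dim(object@distances)
  cat(sprintf("DistanceMap: %d x %d x %d voxels, max distance %.2f mm\n",
              d[1], d[2], d[3], max(object@distances, na.rm = TRUE)))
})

setMethod("show", "RootDistanceHistogram", function(object) {
  cat(sprintf(
    "RootDistanceHistogram: %d bins of %.3g mm, %g voxels, range [0, %.3g] mm\n",
    length(object@counts), object@binWidth, object@nVoxels,
    max(object@breaks)))
  if (object@nVoxels == 0) cat("  (empty histogram)\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (mixed triangular-gamma, binned ML)\n  ")
  show(object@params)
  cat(sprintf("  logLik = %.4g  converged = %s  n = %g\n",
              object@logLik, object@converged, object@nVoxels))
  unc <- names(object@reliability)[object@reliability == "uncertain"]
  if (length(unc))
    cat("  uncertain parameters:", paste(unc, collapse = ", "), "\n")
})

setMethod("show", "PointPattern2D", function(object) {
  win <- if (object@windowShape == "disc")
    sprintf("disc of radius %.4g mm", object@window)
  else
    sprintf("%.4g x %.4g mm window", object@window[1], object@window[2])
  cat(sprintf("PointPattern2D (%s): %d points in %s, density %.4g /mm^2\n",
              object@kind, nrow(object@points), win, object@density))
})

setMethod("show", "RootAgeVolume", function(object) {
  cat(sprintf("RootAgeVolume: %d time steps, %d root voxels\n",
              object@nSteps, sum(object@ages > 0)))
})

#' Is a histogram empty?
#'
#' A slab histogram with no soil voxels is flagged empty rather than raising
#' an error.
#' @param x a \linkS4class{RootDistanceHistogram}.
#' @return TRUE if no soil voxels contributed.
#' @export
isEmptyHistogram <- function(x) {
  stopifnot(is(x, "RootDistanceHistogram"))
  x@nVoxels == 0
}
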