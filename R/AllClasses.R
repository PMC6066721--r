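#' @useDynLib rhizodist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new is validObject slot
#' @importFrom stats dgamma pgamma qgamma rgamma runif rbinom optim integrate
#' @importFrom utils read.csv write.csv
NULL

#' Parameters of the mixed triangular-gamma root distance model
#'
#' Holds the four parameters of the mixed density
#' \deqn{f_{c,k,\theta,p}(d) = c\,f^\Gamma_{k,\theta}(d) + (1-c)\,f^\Delta_p(d)}
#' where \eqn{f^\Gamma} is a gamma density (shape \eqn{k}, scale \eqn{\theta}
#' in mm) describing a developed lateral-root network, and \eqn{f^\Delta} is a
#' triangular density on \eqn{[0, 2p]} describing a single vertical tap root
#' at distance \eqn{p} (mm) from the column wall. The weight \eqn{c \in [0,1]}
#' interpolates between the two architectures.
#'
#' @slot c numeric, mixing weight in [0, 1] for the gamma component.
#' @slot k numeric, dimensionless gamma shape, > 0.
#' @slot theta numeric, gamma scale in mm, > 0.
#' @slot p numeric, tap-root-to-wall distance in mm, > 0.
#' @export
setClass("MixedModelParams",
  representation(c = "numeric", k = "numeric", theta = "numeric",
                 p = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@c) != 1 || is.na(object@c) ||
        object@c < 0 || object@c > 1)
      msg <- c(msg, "'c' must be a single value in [0, 1]")
    if (length(object@k) != 1 || is.na(object@k) || object@k <= 0)
      msg <- c(msg, "'k' must be a single positive value")
    if (length(object@theta) != 1 || is.na(object@theta) || object@theta <= 0)
      msg <- c(msg, "'theta' must be a single positive value (mm)")
    if (length(object@p) != 1 || is.na(object@p) || object@p <= 0)
      msg <- c(msg, "'p' must be a single positive value (mm)")
    if (length(msg)) msg else TRUE
  })

#' Segmented 3D root/soil volume
#'
#' A voxel label grid with values 0 (outside the region of interest),
#' 1 (soil) and 2 (root), plus the physical voxel edge lengths. The first
#' array axis is depth z, increasing downward; axes are (z, y, x).
#'
#' @slot voxels integer 3D array with values in \{0, 1, 2\}.
#' @slot spacing numeric length-3 voxel edge lengths (dz, dy, dx) in mm.
#' @export
setClass("SegmentedVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3)
      msg <- c(msg, "'voxels' must be a 3D array")
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive values (dz, dy, dx) in mm")
    vals <- unique(as.vector(object@voxels))
    if (!all(vals %in% c(0L, 1L, 2L)))
      msg <- c(msg, "voxel labels must be 0 (outside), 1 (soil) or 2 (root)")
    if (length(msg)) msg else TRUE
  })

#' Cylindrical or full-grid region of interest
#'
#' Describes the analysis region: either the full grid, or a vertical
#' cylinder (axis parallel to z) matching the soil column interior.
#' Coordinates are physical (mm); a voxel belongs to the ROI when its center
#' falls inside.
#'
#' @slot shape character, "cylinder" or "full".
#' @slot centerXY numeric length-2 cylinder axis position (x, y) in mm.
#' @slot radius numeric cylinder radius in mm.
#' @slot zRange numeric length-2 depth interval (mm), top < bottom.
#' @export
setClass("RoiMask",
  representation(shape = "character", centerXY = "numeric",
                 radius = "numeric", zRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@shape %in% c("cylinder", "full"))
      msg <- c(msg, "'shape' must be \"cylinder\" or \"full\"")
    if (object@shape == "cylinder") {
      if (length(object@centerXY) != 2)
        msg <- c(msg, "'centerXY' must be (x, y) in mm")
      if (length(object@radius) != 1 || object@radius <= 0)
        msg <- c(msg, "'radius' must be a single positive value (mm)")
    }
    if (length(object@zRange) != 2 || diff(object@zRange) <= 0)
      msg <- c(msg, "'zRange' must be an increasing depth interval (mm)")
    if (length(msg)) msg else TRUE
  })

#' Euclidean distance map of a segmented volume
#'
#' Per-voxel Euclidean distance (mm, center-to-center) to the nearest root
#' voxel, NA on root voxels where the distance is undefined. Carries the soil
#' mask so histograms can be restricted to soil voxels.
#'
#' @slot distances numeric 3D array of distances in mm, NA on root voxels.
#' @slot soil logical 3D array, TRUE where the voxel is soil (label 1).
#' @slot spacing numeric length-3 voxel edge lengths (dz, dy, dx) in mm.
#' @export
setClass("DistanceMap",
  representation(distances = "array", soil = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@distances), dim(object@soil)))
      msg <- c(msg, "'distances' and 'soil' must have identical dimensions")
    if (any(object@distances < 0, na.rm = TRUE))
      msg <- c(msg, "distances must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Root distance histogram (RDH)
#'
#' Relative frequency, over soil voxels in a region of interest, of the
#' Euclidean distance to the nearest root voxel. The relative frequency of a
#' bin is the volume fraction of soil at that distance. Bins are uniform,
#' half-open [left, right), last bin closed.
#'
#' @slot breaks numeric bin edges in mm, strictly increasing, uniform width.
#' @slot counts numeric per-bin soil voxel (or sample) counts.
#' @slot relFreq numeric per-bin relative frequencies, summing to 1.
#' @slot nVoxels numeric total number of contributing soil voxels.
#' @slot binWidth numeric bin width in mm.
#' @export
setClass("RootDistanceHistogram",
  representation(breaks = "numeric", counts = "numeric", relFreq = "numeric",
                 nVoxels = "numeric", binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    nb <- length(object@breaks) - 1L
    if (nb < 1) msg <- c(msg, "at least one bin is required")
    if (any(diff(object@breaks) <= 0))
      msg <- c(msg, "'breaks' must be strictly increasing")
    if (length(object@counts) != nb || length(object@relFreq) != nb)
      msg <- c(msg, "'counts' and 'relFreq' must have one entry per bin")
    if (any(object@relFreq < 0))
      msg <- c(msg, "relative frequencies must be nonnegative")
    if (object@nVoxels > 0 && abs(sum(object@relFreq) - 1) > 1e-9)
      msg <- c(msg, "relative frequencies must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Root age volume
#'
#' Per-voxel integer giving the first time step (1-based) at which the voxel
#' was classified as root in a registered time series; 0 where the voxel was
#' never root.
#'
#' @slot ages integer 3D array of first-appearance time steps, 0 = never root.
#' @slot nSteps integer number of time steps in the series.
#' @slot spacing numeric length-3 voxel edge lengths (dz, dy, dx) in mm.
#' @export
setClass("RootAgeVolume",
  representation(ages = "array", nSteps = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@ages < 0) || any(object@ages > object@nSteps))
      msg <- c(msg, "ages must lie in 0..nSteps")
    if (length(msg)) msg else TRUE
  })

#' Result of fitting the mixed triangular-gamma model
#'
#' @slot params \linkS4class{MixedModelParams} at the optimum.
#' @slot logLik numeric binned multinomial log-likelihood at the optimum.
#' @slot converged logical, TRUE if any optimizer start converged.
#' @slot reliability named character flags ("reliable"/"uncertain") for k,
#'   theta and p: when c < 0.15 the gamma parameters (k, theta) are
#'   non-identifiable, when c > 0.85 the triangular parameter p is.
#' @slot nVoxels numeric number of soil voxels behind the fitted histogram.
#' @export
setClass("FitResult",
  representation(params = "MixedModelParams", logLik = "numeric",
                 converged = "logical", reliability = "character",
                 nVoxels = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("k", "theta", "p") %in% names(object@reliability)))
      msg <- c(msg, "'reliability' needs flags for k, theta and p")
    if (!all(object@reliability %in% c("reliable", "uncertain")))
      msg <- c(msg, "reliability flags must be 'reliable' or 'uncertain'")
    if (length(msg)) msg else TRUE
  })

#' Planar root point pattern
#'
#' Positions of parallel roots in a 2D cross section, either on a hexagonal
#' (triangular) lattice or uniformly at random. The window is either a
#' rectangle with origin (0, 0) and extent (width, height), or a disc of
#' given radius centered at the origin (the circular soil-column cross
#' section).
#'
#' @slot points numeric n x 2 matrix of (x, y) positions in mm.
#' @slot window numeric: (width, height) in mm for a rectangle, radius in mm
#'   for a disc.
#' @slot windowShape character, "rect" or "disc".
#' @slot density numeric nominal point density (points per mm^2).
#' @slot kind character, "hexagonal" or "random".
#' @export
setClass("PointPattern2D",
  representation(points = "matrix", window = "numeric",
                 windowShape = "character", density = "numeric",
                 kind = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != 2)
      msg <- c(msg, "'points' must be an n x 2 matrix")
    if (!object@kind %in% c("hexagonal", "random"))
      msg <- c(msg, "'kind' must be \"hexagonal\" or \"random\"")
    if (!object@windowShape %in% c("rect", "disc"))
      msg <- c(msg, "'windowShape' must be \"rect\" or \"disc\"")
    if (object@windowShape == "rect" &&
        (length(object@window) != 2 || any(object@window <= 0)))
      msg <- c(msg, "'window' must be positive (width, height) in mm")
    if (object@windowShape == "disc" &&
        (length(object@window) != 1 || object@window <= 0))
      msg <- c(msg, "'window' must be a positive disc radius in mm")
    if (object@density <= 0) msg <- c(msg, "'density' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic tap-root + laterals root system
#'
#' Describes a vertical tap root with whorls of first-order laterals inside a
#' cylindrical soil column, used to generate voxelized test volumes with
#' exactly known root length density.
#'
#' @slot columnHeight numeric column height (mm), default 250.
#' @slot columnRadius numeric column radius (mm), default 35.
#' @slot taprootXY numeric length-2 tap root (x, y) position in mm, measured
#'   in grid coordinates (the column axis sits at the grid center).
#' @slot taprootDepth numeric depth reached by the tap root (mm).
#' @slot taprootRadius numeric tap root radius (mm).
#' @slot lateralSpacing numeric vertical spacing of lateral whorls (mm).
#' @slot lateralsPerWhorl integer number of laterals per whorl.
#' @slot lateralAngle numeric elevation angle of laterals below the
#'   horizontal, degrees.
#' @slot lateralLength numeric final lateral length (mm).
#' @slot lateralRadius numeric lateral root radius (mm).
#' @slot seed integer seed for the random azimuth phase of each whorl.
#' @export
setClass("RootSystemSpec",
  representation(columnHeight = "numeric", columnRadius = "numeric",
                 taprootXY = "numeric", taprootDepth = "numeric",
                 taprootRadius = "numeric", lateralSpacing = "numeric",
                 lateralsPerWhorl = "integer", lateralAngle = "numeric",
                 lateralLength = "numeric", lateralRadius = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@columnHeight <= 0 || object@columnRadius <= 0)
      msg <- c(msg, "column dimensions must be positive")
    if (sqrt(sum((object@taprootXY - object@columnRadius)^2)) >
        object@columnRadius)
      msg <- c(msg, "tap root must lie inside the column")
    if (object@taprootRadius <= 0 || object@lateralRadius <= 0)
      msg <- c(msg, "root radii must be positive")
    if (object@lateralSpacing <= 0)
      msg <- c(msg, "'lateralSpacing' must be positive")
    if (object@taprootDepth <= 0 || object@taprootDepth > object@columnHeight)
      msg <- c(msg, "'taprootDepth' must lie in (0, columnHeight]")
    if (length(msg)) msg else TRUE
  })

#' Growth timeline for a synthetic root system
#'
#' Per-time-step tap root depth and lateral elongation increment. Tap depth
#' is nondecreasing; laterals of a whorl start growing at the first step
#' whose tap depth reaches the whorl, then elongate by the per-step increment
#' up to the final length in the system spec. Root sets are nested over time.
#'
#' @slot tapDepth numeric per-step tap root depth (mm), nondecreasing.
#' @slot lateralGrowth numeric per-step lateral elongation increment (mm).
#' @export
setClass("GrowthTimeline",
  representation(tapDepth = "numeric", lateralGrowth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tapDepth) != length(object@lateralGrowth))
      msg <- c(msg, "'tapDepth' and 'lateralGrowth' must have equal length")
    if (any(diff(object@tapDepth) < 0))
      msg <- c(msg, "'tapDepth' must be nondecreasing")
    if (any(object@lateralGrowth < 0))
      msg <- c(msg, "'lateralGrowth' must be nonnegative")
    if (length(msg)) msg else TRUE
  })
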