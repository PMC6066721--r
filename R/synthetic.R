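#' Specify a synthetic tap-root + laterals system
#'
#' Defaults emulate a dicot seedling (vertical tap root with whorls of
#' first-order laterals, no second-order laterals) in the standard soil
#' column geometry: 250 mm height, 35 mm radius. The tap root sits
#' off-center, as commonly observed in pot experiments; the grid spans the
#' column diameter and the column axis sits at the grid center.
#'
#' @param columnHeight column height in mm.
#' @param columnRadius column radius in mm.
#' @param taprootXY tap root (x, y) in mm in grid coordinates; default is
#'   10 mm off-axis.
#' @param taprootDepth depth reached by the tap root (mm).
#' @param taprootRadius tap root radius (mm).
#' @param lateralSpacing vertical spacing between lateral whorls (mm).
#' @param lateralsPerWhorl laterals per whorl.
#' @param lateralAngle lateral elevation below horizontal (degrees).
#' @param lateralLength final lateral length (mm).
#' @param lateralRadius lateral radius (mm).
#' @param seed integer seed controlling the azimuth phase of each whorl.
#' @return A \linkS4class{RootSystemSpec}.
#' @export
rootSystemSpec <- function(columnHeight = 250, columnRadius = 35,
                           taprootXY = c(columnRadius + 10, columnRadius),
                           taprootDepth = columnHeight * 0.9,
                           taprootRadius = 1.5,
                           lateralSpacing = 5, lateralsPerWhorl = 5L,
                           lateralAngle = 20, lateralLength = 40,
                           lateralRadius = 0.6, seed = 1L) {
  new("RootSystemSpec", columnHeight = columnHeight,
      columnRadius = columnRadius, taprootXY = as.numeric(taprootXY),
      taprootDepth = taprootDepth, taprootRadius = taprootRadius,
      lateralSpacing = lateralSpacing,
      lateralsPerWhorl = as.integer(lateralsPerWhorl),
      lateralAngle = lateralAngle, lateralLength = lateralLength,
      lateralRadius = lateralRadius, seed = as.integer(seed))
}

#' @describeIn growTimeSeries Construct a growth timeline.
#' @param tapDepth per-step tap root depth (mm), nondecreasing.
#' @param lateralGrowth per-step lateral elongation (mm); scalar recycled.
#' @export
growthTimeline <- function(tapDepth, lateralGrowth) {
  if (length(lateralGrowth) == 1)
    lateralGrowth <- rep(lateralGrowth, length(tapDepth))
  new("GrowthTimeline", tapDepth = as.numeric(tapDepth),
      lateralGrowth = as.numeric(lateralGrowth))
}

# Whorl azimuth phases, deterministic in the spec seed, shared across all
# time steps so that growing root sets stay nested.
.whorlPhases <- function(spec) {
  nmax <- floor(spec@columnHeight / spec@lateralSpacing)
  withr_seed <- spec@seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                    .GlobalEnv) else NULL
  set.seed(withr_seed)
  ph <- runif(max(nmax, 1), 0, 2 * pi)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ph
}

# Centerline segments (start, end in (z, y, x) mm, radius) of the system at
# a given tap depth with a per-whorl lateral length function.
.rootSegments <- function(spec, tapDepth, lateralLenFun) {
  segs <- list(list(
    a = c(0, spec@taprootXY[2], spec@taprootXY[1]),
    b = c(tapDepth, spec@taprootXY[2], spec@taprootXY[1]),
    radius = spec@taprootRadius))
  phases <- .whorlPhases(spec)
  depths <- seq(spec@lateralSpacing, spec@columnHeight,
                by = spec@lateralSpacing)
  elev <- spec@lateralAngle * pi / 180
  for (w in seq_along(depths)) {
    zw <- depths[w]
    if (zw > tapDepth) next
    len <- lateralLenFun(w)
    if (len <= 0) next
    for (j in seq_len(spec@lateralsPerWhorl)) {
      az <- phases[w] + 2 * pi * (j - 1) / spec@lateralsPerWhorl
      dir <- c(sin(elev), cos(elev) * sin(az), cos(elev) * cos(az))
      a <- c(zw, spec@taprootXY[2], spec@taprootXY[1])
      segs[[length(segs) + 1]] <- list(a = a, b = a + len * dir,
                                       radius = spec@lateralRadius)
    }
  }
  segs
}

# Length of a segment clipped to the column interior (cylinder of radius R
# around the grid center, depth 0..H). Start point assumed inside.
.clippedLength <- function(a, b, center, R, H) {
  v <- b - a
  L <- sqrt(sum(v^2))
  if (L == 0) return(0)
  u <- v / L
  tmax <- L
  # radial exit: |(a_xy - c) + t u_xy|^2 = R^2
  w <- c(a[2] - center[2], a[3] - center[1])
  uxy <- c(u[2], u[3])
  A <- sum(uxy^2)
  B <- 2 * sum(w * uxy)
  C <- sum(w^2) - R^2
  if (A > 0) {
    disc <- B^2 - 4 * A * C
    if (disc >= 0) {
      t2 <- (-B + sqrt(disc)) / (2 * A)
      if (t2 >= 0) tmax <- min(tmax, t2)
    }
  } else if (C > 0) return(0)
  # depth exit
  if (u[1] > 0) tmax <- min(tmax, (H - a[1]) / u[1])
  if (u[1] < 0) tmax <- min(tmax, (0 - a[1]) / u[1])
  max(tmax, 0)
}

.rasterize <- function(spec, segments, voxelSize) {
  R <- spec@columnRadius
  H <- spec@columnHeight
  nz <- as.integer(ceiling(H / voxelSize))
  nxy <- as.integer(ceiling(2 * R / voxelSize))
  dims <- c(nz, nxy, nxy)
  spacing <- rep(voxelSize, 3)
  # soil inside the cylinder, outside elsewhere
  yc <- (seq_len(nxy) - 0.5) * voxelSize
  r2 <- outer((yc - R)^2, (yc - R)^2, "+")
  inCyl <- r2 <= R^2
  labels <- array(0L, dims)
  for (z in seq_len(nz)) labels[z, , ] <- ifelse(inCyl, 1L, 0L)
  lab <- as.integer(labels)
  clipped <- FALSE
  for (s in segments) {
    lab <- rasterize_segment(lab, dims, spacing, s$a, s$b, s$radius)
    if (.clippedLength(s$a, s$b, c(R, R), R, H) <
        sqrt(sum((s$b - s$a)^2)) - 1e-9)
      clipped <- TRUE
  }
  if (clipped)
    warning("some root segments leave the column and were clipped")
  dim(lab) <- dims
  segmentedVolume(lab, spacing)
}

.groundTruth <- function(spec, segments) {
  R <- spec@columnRadius
  H <- spec@columnHeight
  totLen <- sum(vapply(segments, function(s)
    .clippedLength(s$a, s$b, c(R, R), R, H), numeric(1)))
  vol <- pi * R^2 * H                      # mm^3
  list(totalLength_mm = totLen,
       # (L/10 cm) / (V/1000 cm^3) = 100 L/V
       R_L_cm_per_cm3 = 100 * totLen / vol,
       surface_cm2_per_cm3 = 10 * sum(vapply(segments, function(s)
         2 * pi * s$radius * .clippedLength(s$a, s$b, c(R, R), R, H),
         numeric(1))) / vol)
}

#' Rasterize a synthetic root system
#'
#' Labels every voxel whose center lies within a root segment's radius of
#' its centerline as root, inside a cylindrical soil column. Ground-truth
#' root length density is computed analytically from the clipped centerline
#' lengths, not from voxel counts.
#'
#' @param spec a \linkS4class{RootSystemSpec}.
#' @param voxelSize voxel edge length in mm; must not exceed the smallest
#'   root radius.
#' @param lateralLength overrides the spec's lateral length (e.g. 0 for a
#'   tap-root-only system); NULL uses the spec value.
#' @return List with elements \code{volume} (\linkS4class{SegmentedVolume}),
#'   \code{R_L_cm_per_cm3}, \code{surface_cm2_per_cm3} and
#'   \code{totalLength_mm} (analytic ground truth).
#' @examples
#' sys <- rasterizeRootSystem(
#'   rootSystemSpec(columnHeight = 40, columnRadius = 12,
#'                  taprootXY = c(16, 12), taprootDepth = 36,
#'                  lateralLength = 8), voxelSize = 1)
#' @export
rasterizeRootSystem <- function(spec, voxelSize, lateralLength = NULL) {
  stopifnot(is(spec, "RootSystemSpec"))
  validObject(spec)
  if (voxelSize > min(spec@taprootRadius, spec@lateralRadius))
    stop("'voxelSize' must not exceed the smallest root radius",
         call. = FALSE)
  latLen <- if (is.null(lateralLength)) spec@lateralLength else lateralLength
  segs <- .rootSegments(spec, spec@taprootDepth, function(w) latLen)
  vol <- .rasterize(spec, segs, voxelSize)
  c(list(volume = vol), .groundTruth(spec, segs))
}

#' Grow a synthetic root system over discrete time steps
#'
#' Produces a perfectly registered series of segmented volumes on one grid.
#' The tap root deepens according to the timeline; each lateral whorl starts
#' growing at the first step whose tap depth reaches it and then elongates
#' by the per-step increment up to the spec's final length. Root sets are
#' nested over time, making the series a valid input for
#' \code{\link{buildAgeVolume}}.
#'
#' @param spec a \linkS4class{RootSystemSpec}.
#' @param timeline a \linkS4class{GrowthTimeline}.
#' @param voxelSize voxel edge length in mm.
#' @return List of \linkS4class{SegmentedVolume}, one per step, with the
#'   per-step analytic ground truth attached as attribute
#'   \code{"groundTruth"}.
#' @export
growTimeSeries <- function(spec, timeline, voxelSize) {
  stopifnot(is(spec, "RootSystemSpec"), is(timeline, "GrowthTimeline"))
  validObject(timeline)
  nT <- length(timeline@tapDepth)
  depths <- seq(spec@lateralSpacing, spec@columnHeight,
                by = spec@lateralSpacing)
  # activation step of each whorl: first step whose tap depth reaches it
  act <- vapply(depths, function(zw) {
    i <- which(timeline@tapDepth >= zw)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  out <- vector("list", nT)
  gt <- vector("list", nT)
  for (t in seq_len(nT)) {
    lenFun <- function(w) {
      if (is.na(act[w]) || act[w] > t) return(0)
      min(sum(timeline@lateralGrowth[act[w]:t]), spec@lateralLength)
    }
    segs <- .rootSegments(spec, timeline@tapDepth[t], lenFun)
    out[[t]] <- .rasterize(spec, segs, voxelSize)
    gt[[t]] <- .groundTruth(spec, segs)
  }
  attr(out, "groundTruth") <- gt
  out
}
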