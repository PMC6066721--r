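#' Hexagonal root point pattern
#'
#' Triangular-lattice positions of parallel roots in a 2D cross section, the
#' equidistant reference configuration behind the half-mean distance formula.
#' The lattice spacing s solves \eqn{2 / (\sqrt{3} s^2) = density}.
#'
#' Two constructions are supported. With a rectangular \code{window}, the
#' lattice is centered in the window and clipped to it. With \code{window =
#' NULL} (the default), a complete hexagonal bundle of \code{rings} rings
#' around a central root (\eqn{N = 1 + 3k(k+1)} roots) is placed at the
#' center of a disc-shaped cross section whose area is exactly \eqn{N /
#' density}, so the bundle's root length density matches the nominal density
#' by construction — the bounded root bundle in a circular soil column that
#' the mean-distance-to-HMD ratio refers to.
#'
#' @param density points per mm^2.
#' @param window rectangle extent (width, height) in mm, or NULL for the
#'   disc-bundle construction.
#' @param rings number of complete lattice rings of the disc bundle.
#' @return A \linkS4class{PointPattern2D} of kind "hexagonal".
#' @examples
#' hexagonalPattern(0.01)                      # 127-root bundle in a disc
#' hexagonalPattern(0.01, window = c(200, 200))
#' @export
hexagonalPattern <- function(density, window = NULL, rings = 6L) {
  stopifnot(density > 0)
  s <- sqrt(2 / (sqrt(3) * density))
  if (is.null(window)) {
    stopifnot(rings >= 1)
    pts <- matrix(c(0, 0), 1)
    for (ring in seq_len(rings)) {
      ang <- (0:5) * pi / 3
      corners <- cbind(ring * s * cos(ang), ring * s * sin(ang))
      for (j in 1:6) {
        a <- corners[j, ]
        b <- corners[j %% 6 + 1, ]
        for (t in 0:(ring - 1))
          pts <- rbind(pts, a + (b - a) * t / ring)
      }
    }
    radius <- sqrt(nrow(pts) / density / pi)
    return(new("PointPattern2D", points = unname(pts), window = radius,
               windowShape = "disc", density = density, kind = "hexagonal"))
  }
  stopifnot(length(window) == 2, all(window > 0))
  rowSep <- s * sqrt(3) / 2
  nx <- ceiling(window[1] / s) + 2L
  ny <- ceiling(window[2] / rowSep) + 2L
  pts <- do.call(rbind, lapply(seq_len(ny), function(j) {
    off <- if (j %% 2 == 0) s / 2 else 0
    cbind(x = (seq_len(nx) - 1) * s + off, y = (j - 1) * rowSep)
  }))
  # center the lattice in the window
  pts[, 1] <- pts[, 1] - (max(pts[, 1]) + min(pts[, 1])) / 2 + window[1] / 2
  pts[, 2] <- pts[, 2] - (max(pts[, 2]) + min(pts[, 2])) / 2 + window[2] / 2
  keep <- pts[, 1] >= 0 & pts[, 1] <= window[1] &
    pts[, 2] >= 0 & pts[, 2] <= window[2]
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 7)
    stop("window too small for the requested density ",
         "(fewer than 7 lattice points)", call. = FALSE)
  new("PointPattern2D", points = unname(pts), window = as.numeric(window),
      windowShape = "rect", density = density, kind = "hexagonal")
}

#' Random (binomial) root point pattern
#'
#' Uniform i.i.d. root positions in the window; the point count is fixed to
#' round(density * area) so that the pattern's root length density is known
#' exactly for ratio computations (binomial approximation of a Poisson
#' pattern).
#'
#' @param density points per mm^2.
#' @param window rectangle extent (width, height) in mm.
#' @param seed integer seed; the same seed reproduces the pattern.
#' @return A \linkS4class{PointPattern2D} of kind "random" whose
#'   \code{density} slot holds the exact realized density n / area.
#' @export
poissonPattern <- function(density, window = c(200, 200), seed = 1L) {
  stopifnot(density > 0, length(window) == 2, all(window > 0))
  area <- prod(window)
  n <- max(1L, as.integer(round(density * area)))
  set.seed(as.integer(seed))
  pts <- cbind(runif(n, 0, window[1]), runif(n, 0, window[2]))
  new("PointPattern2D", points = pts, window = as.numeric(window),
      windowShape = "rect", density = n / area, kind = "random")
}

#' Monte Carlo distance statistics of a point pattern
#'
#' Samples uniform probe locations in the pattern's window, measures the
#' distance to the nearest root (pattern point), and relates the mean to the
#' theoretical half-mean distance \eqn{HMD = (\pi \rho)^{-1/2}} at the
#' pattern's density. Disc-bundle and random patterns are probed over the
#' full cross section, so the mild edge effects of a bounded sample are part
#' of the statistic; a rectangular hexagonal lattice is probed on the window
#' shrunk by one lattice spacing and yields the pure interior lattice value
#' (about 0.67).
#'
#' @param pattern a \linkS4class{PointPattern2D}.
#' @param nProbe number of probe points (default 1e5).
#' @param seed integer seed for the probe locations.
#' @param binWidth bin width of the normalized-distance histogram, in units
#'   of HMD.
#' @return List with \code{meanDistance} (mm), \code{hmd} (mm),
#'   \code{ratio} (meanDistance / hmd) and \code{rdh}, a
#'   \linkS4class{RootDistanceHistogram} of d / HMD.
#' @examples
#' patternDistanceStats(hexagonalPattern(0.01), nProbe = 1e4, seed = 1)$ratio
#' @export
patternDistanceStats <- function(pattern, nProbe = 1e5, seed = 1L,
                                 binWidth = 0.05) {
  stopifnot(is(pattern, "PointPattern2D"))
  if (nrow(pattern@points) == 0)
    stop("degenerate pattern with no points", call. = FALSE)
  set.seed(as.integer(seed))
  if (pattern@windowShape == "disc") {
    R <- pattern@window
    r <- R * sqrt(runif(nProbe))
    th <- runif(nProbe, 0, 2 * pi)
    px <- r * cos(th)
    py <- r * sin(th)
  } else {
    lo <- c(0, 0)
    hi <- pattern@window
    if (pattern@kind == "hexagonal") {
      s <- sqrt(2 / (sqrt(3) * pattern@density))
      lo <- lo + s
      hi <- hi - s
      if (any(hi <= lo))
        stop("window too small to shrink by one lattice spacing",
             call. = FALSE)
    }
    px <- runif(nProbe, lo[1], hi[1])
    py <- runif(nProbe, lo[2], hi[2])
  }
  nd <- nearest_point_dist(px, py, pattern@points[, 1], pattern@points[, 2])
  hmdMm <- (pi * pattern@density)^(-0.5)
  list(meanDistance = mean(nd), hmd = hmdMm, ratio = mean(nd) / hmdMm,
       rdh = rdhFromSamples(nd / hmdMm, binWidth))
}
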