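#' Read and write segmented volumes as multi-page TIFF
#'
#' One page per z slice, 8-bit labels: 0 = outside, 1 = soil, 2 = root.
#' The voxel size is never parsed from TIFF tags (CT export conventions
#' vary); it must be supplied explicitly.
#'
#' @param volume a \linkS4class{SegmentedVolume}.
#' @param path TIFF file path.
#' @return \code{writeSegmentedVolume} returns the path invisibly;
#'   \code{readSegmentedVolume} returns a \linkS4class{SegmentedVolume}.
#' @export
writeSegmentedVolume <- function(volume, path) {
  stopifnot(is(volume, "SegmentedVolume"))
  pages <- lapply(seq_len(dim(volume@voxels)[1]), function(z)
    volume@voxels[z, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeSegmentedVolume
#' @param spacing voxel edge lengths (dz, dy, dx) in mm, or one value for
#'   isotropic voxels.
#' @export
readSegmentedVolume <- function(path, spacing) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- c(length(pages), dim(pages[[1]]))
  vox <- array(0L, dims)
  for (z in seq_along(pages))
    vox[z, , ] <- as.integer(round(pages[[z]] * 255))
  bad <- setdiff(unique(as.vector(vox)), c(0L, 1L, 2L))
  if (length(bad))
    stop("TIFF contains label values outside {0, 1, 2}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  segmentedVolume(vox, spacing)
}

#' Read and write root distance histograms as CSV
#'
#' Columns: bin_left_mm, bin_right_mm, rel_freq, count. The round trip is
#' lossless.
#'
#' @param rdh a \linkS4class{RootDistanceHistogram}.
#' @param path CSV file path.
#' @export
writeRdh <- function(rdh, path) {
  stopifnot(is(rdh, "RootDistanceHistogram"))
  df <- data.frame(bin_left_mm = rdh@breaks[-length(rdh@breaks)],
                   bin_right_mm = rdh@breaks[-1],
                   rel_freq = rdh@relFreq, count = rdh@counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRdh
#' @export
readRdh <- function(path) {
  df <- read.csv(path)
  need <- c("bin_left_mm", "bin_right_mm", "rel_freq", "count")
  if (!all(need %in% names(df)))
    stop("malformed histogram CSV; expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  n <- sum(df$count)
  new("RootDistanceHistogram",
      breaks = c(df$bin_left_mm, df$bin_right_mm[nrow(df)]),
      counts = df$count,
      relFreq = if (n > 0) df$count / n else df$rel_freq,
      nVoxels = n,
      binWidth = df$bin_right_mm[1] - df$bin_left_mm[1])
}

#' Write a fit result as JSON
#'
#' Schema: \code{\{c, k, theta_mm, p_mm, loglik, converged,
#' reliability: \{k, theta, p\}, n_voxels\}}.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param path JSON file path.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  pp <- fit@params
  jsonlite::write_json(list(
    c = pp@c, k = pp@k, theta_mm = pp@theta, p_mm = pp@p,
    loglik = fit@logLik, converged = fit@converged,
    reliability = as.list(fit@reliability), n_voxels = fit@nVoxels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
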