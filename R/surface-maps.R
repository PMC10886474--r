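## Map pre-normalisation, artifact screening and cropping.

#' Remove the least-squares plane tilt from a map
#'
#' Subtracts the least-squares plane (offset + x gradient + y gradient);
#' the output has exactly zero mean.  In the default pipeline this is
#' applied to height maps only: the absolute height origin is arbitrary,
#' whereas adhesion channels are used as is.
#'
#' @param map a [SurfaceMap]
#' @return A [SurfaceMap] with the plane removed.
#' @examples
#' m <- generateSurface(surfaceConfig(gridSize = 64,
#'                                    planeTilt = c(0.01, -0.02)),
#'                      seed = 1, channel = "height", units = "nm")
#' removePlaneTilt(m)
#' @export
removePlaneTilt <- function(map) {
  stopifnot(is(map, "SurfaceMap"))
  z <- map@values
  m <- nrow(z)
  ## column-major flattening: row index varies fastest
  x <- rep(seq_len(m) - (m + 1) / 2, each = m)    # column coordinate
  y <- rep(seq_len(m) - (m + 1) / 2, times = m)   # row coordinate
  ## centred coordinates are orthogonal, so the fit reduces to projections
  zv <- as.numeric(z)
  bx <- sum(zv * x) / sum(x * x)
  by <- sum(zv * y) / sum(y * y)
  res <- matrix(zv - mean(zv) - bx * x - by * y, m, m)
  out <- map
  out@values <- res
  out@metadata$tiltRemoved <- TRUE
  out
}

#' Screen a map for scanning artifacts
#'
#' Automated proxies for visual artifact inspection: the line-artifact
#' score is the largest jump between adjacent row medians relative to the
#' map RMS (scan-line offsets), the spike fraction is the fraction of
#' pixels deviating more than 6 MAD from the median (debris, glitches),
#' and the saturation fraction is the fraction of pixels sitting at the
#' extreme recorded values (range clipping).  A map passes when all three
#' scores are below their thresholds.
#'
#' @param map a [SurfaceMap]
#' @param thresholds list with elements `lineArtifact` (default 1.0),
#'   `spikeFraction` (default 0.01) and `saturationFraction`
#'   (default 0.001)
#' @return A [QCReport].
#' @export
screenMap <- function(map,
                      thresholds = list(lineArtifact = 1.0,
                                        spikeFraction = 0.01,
                                        saturationFraction = 0.001)) {
  stopifnot(is(map, "SurfaceMap"))
  z <- map@values
  d <- z - mean(z)
  s <- rmsAboutMean(z)
  rowMed <- apply(z, 1, stats::median)
  lineScore <- if (s > 0) max(abs(diff(rowMed))) / s else 0
  md <- stats::median(z)
  madv <- stats::mad(z)
  spikeFrac <- if (madv > 0) mean(abs(z - md) > 6 * madv) else 0
  zr <- range(z)
  satFrac <- if (zr[2] > zr[1])
    (sum(z == zr[1]) + sum(z == zr[2])) / length(z) else 0
  passed <- lineScore < thresholds$lineArtifact &&
    spikeFrac < thresholds$spikeFraction &&
    satFrac < thresholds$saturationFraction
  new("QCReport", lineArtifactScore = lineScore,
      spikeFraction = spikeFrac, saturationFraction = satFrac,
      passed = passed, thresholds = thresholds)
}

#' Crop a square region out of a map
#'
#' @param map a [SurfaceMap]
#' @param center length-2 pixel coordinates (row, column) of the crop
#'   centre
#' @param size crop size in pixels (even)
#' @return A [SurfaceMap] of size `size` with the pixel pitch preserved.
#' @export
cropRegion <- function(map, center, size) {
  stopifnot(is(map, "SurfaceMap"))
  m <- nrow(map@values)
  size <- as.integer(size)
  if (size %% 2L != 0L) stop("crop size must be even")
  r0 <- as.integer(center[1]) - size %/% 2L + 1L
  c0 <- as.integer(center[2]) - size %/% 2L + 1L
  if (r0 < 1L || c0 < 1L || r0 + size - 1L > m || c0 + size - 1L > m)
    stop("crop window exceeds the map bounds")
  out <- map
  out@values <- map@values[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
  out@metadata$crop <- list(center = center, size = size)
  out
}
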