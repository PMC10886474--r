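## 2D amplitude spectra and the spatial indices Stdi, Srwi, Shw.
##
## Conventions (documented, switchable where noted):
##  * the map mean is subtracted before the DFT; no window is applied,
##  * the spectrum is quadrant-swapped so the DC bin sits at the centre
##    pixel (M/2, M/2 zero-based; (M/2+1, M/2+1) in R's 1-based indexing),
##  * angular and radial reductions use the upper half plane only (the
##    modulus spectrum of a real map is Hermitian, so the lower half
##    duplicates it) and always exclude the DC bin,
##  * half-plane pixels are assigned to lines/semicircles by nearest angle
##    (sector binning) and rounded integer radius, which conserves the total
##    amplitude and admits an exact brute-force oracle.

## Centred coordinate grids and half-plane mask for an M x M spectrum.
.spectrumGeometry <- function(m) {
  centre <- m %/% 2 + 1L
  kx <- matrix(rep(seq_len(m) - centre, each = m), m)      # column offset
  ky <- matrix(rep(seq_len(m) - centre, times = m), m)     # row offset
  half <- (ky > 0) | (ky == 0 & kx > 0)
  list(kx = kx, ky = ky, half = half, centre = centre)
}

#' DC-centred 2D amplitude spectrum of a surface map
#'
#' Computes the modulus of the 2D discrete Fourier transform of the
#' mean-subtracted map, quadrant-swapped so the DC component lies at the
#' centre pixel, and derives the angular spectrum, the radial spectrum and
#' its cumulative (integral) form.
#'
#' @param map a [SurfaceMap] (or a square numeric matrix)
#' @param nLines number of equiangular lines for the angular spectrum;
#'   defaults to the image size M
#' @param pixelPitch pixel pitch in nm, required when `map` is a bare matrix
#' @param method angular spectrum method, `"line"` (bilinear sampling at
#'   integer radii along each radial line, so every direction is sampled
#'   at the same radii; the default) or `"sector"` (nearest-line pixel
#'   binning, which admits an exact brute-force oracle)
#' @return A [SpectrumSet].
#' @examples
#' sp <- amplitudeSpectrum(generateSurface(surfaceConfig(), seed = 1))
#' sTdi(sp); sRwi(sp); sHw(sp)
#' @seealso [angularSpectrum()], [radialSpectrum()], [sTdi()], [sRwi()],
#'   [sHw()]
#' @export
amplitudeSpectrum <- function(map, nLines = NULL, pixelPitch = NULL,
                              method = c("line", "sector")) {
  method <- match.arg(method)
  if (is(map, "SurfaceMap")) {
    v <- map@values
    pitch <- map@pixelPitch
  } else {
    v <- as.matrix(map)
    if (is.null(pixelPitch))
      stop("pixelPitch must be given when 'map' is a bare matrix")
    pitch <- pixelPitch
  }
  if (nrow(v) != ncol(v)) stop("the map must be square")
  m <- nrow(v)
  if (is.null(nLines)) nLines <- m
  amp <- fftShift2(Mod(stats::fft(v - mean(v)))) / length(v)
  spec <- new("SpectrumSet", amplitude = amp, angular = numeric(0),
              radial = numeric(0), integralRadial = numeric(0),
              radialCounts = numeric(0), gridSize = as.integer(m),
              pixelPitch = pitch, nLines = as.integer(nLines))
  spec@angular <- angularSpectrum(spec, nLines = nLines, method = method)
  rad <- radialSpectrum(spec, withCounts = TRUE)
  spec@radial <- rad$beta
  spec@radialCounts <- rad$counts
  ## the integral (cumulative) radial spectrum is built on the
  ## count-normalised profile -- mean amplitude per semicircle -- so that
  ## every wavelength enters on an equal footing (see sRwi); the raw sums
  ## are kept in the `radial` slot, where they conserve the total
  ## half-plane amplitude
  prof <- ifelse(rad$counts > 0, rad$beta / pmax(rad$counts, 1), 0)
  spec@integralRadial <- cumsum(prof)
  spec
}

#' Angular spectrum: line amplitudes at equiangular half-plane angles
#'
#' Each off-DC pixel of the upper half plane is assigned to the nearest of
#' `nLines` lines at angles `alpha_i = i * pi / nLines`
#' (`i = 0 .. nLines - 1`).  With the default `normalized = TRUE`, `A(i)`
#' is the mean amplitude of the assigned pixels, so that every direction
#' is represented on an equal footing: the number of lattice pixels per
#' nearest-angle sector varies strongly with direction, and raw sums would
#' make even an isotropic surface look directional.  With
#' `normalized = FALSE` the raw sector sums are returned.  With
#' `method = "line"` the amplitude is instead sampled (bilinearly) along
#' each line at integer radii and averaged.
#'
#' The angle refers to the wave-vector direction in the spectrum: a wave
#' varying along image x (stripes perpendicular to x) has its spectral
#' peaks on the kx axis, i.e. at line angle 0.
#'
#' @param spec a [SpectrumSet] with the 2D amplitude filled in
#' @param nLines number of lines (default: slot value, i.e. image size)
#' @param method `"sector"` or `"line"`, see [amplitudeSpectrum()]
#' @param normalized divide each line by its pixel count (default TRUE)
#' @return Numeric vector `A` of length `nLines` (lines with no assigned
#'   pixels report 0).
#' @export
angularSpectrum <- function(spec, nLines = NULL,
                            method = c("line", "sector"),
                            normalized = TRUE) {
  method <- match.arg(method)
  m <- spec@gridSize
  if (is.null(nLines)) nLines <- spec@nLines
  nLines <- as.integer(nLines)
  amp <- spec@amplitude
  geo <- .spectrumGeometry(m)
  if (method == "sector") {
    theta <- atan2(geo$ky[geo$half], geo$kx[geo$half])  # in [0, pi)
    i <- as.integer(round(theta / (pi / nLines))) %% nLines
    a <- numeric(nLines)
    cnt <- numeric(nLines)
    sums <- rowsum(amp[geo$half], i)
    a[as.integer(rownames(sums)) + 1L] <- sums[, 1]
    tab <- table(i)
    cnt[as.integer(names(tab)) + 1L] <- as.numeric(tab)
    if (normalized) a <- ifelse(cnt > 0, a / pmax(cnt, 1), 0)
    a
  } else {
    ## each line has a finite angular acceptance of one line spacing:
    ## sample five sub-angles per line and average, so adjacent lines
    ## tile the half plane without gaps
    radii <- seq_len(m %/% 2 - 1L)
    step <- pi / nLines
    alpha0 <- (seq_len(nLines) - 1L) * step
    offs <- step * c(-0.4, -0.2, 0, 0.2, 0.4)
    acc <- matrix(0, length(radii), nLines)
    for (off in offs) {
      px <- outer(radii, cos(alpha0 + off))   # column offsets
      py <- outer(radii, sin(alpha0 + off))   # row offsets
      acc <- acc + .bilinear(amp, geo$centre + py, geo$centre + px) /
        length(offs)
    }
    a <- if (normalized) colMeans(acc, na.rm = TRUE) else
      colSums(acc, na.rm = TRUE)
    ## circular 5-tap neighbourhood average: lines are not independent
    ## measurements of direction at this angular resolution, and the
    ## averaging makes the dominant-direction peak robust to single-line
    ## speckle
    n <- length(a)
    if (n >= 5) {
      sm <- a
      for (k in c(-2L, -1L, 1L, 2L))
        sm <- sm + a[(seq_len(n) - 1L + k) %% n + 1L]
      a <- sm / 5
    }
    a
  }
}

## Bilinear interpolation of matrix `z` at (row, col) positions given as
## matrices; positions outside the grid give NA.
.bilinear <- function(z, r, cc) {
  m <- nrow(z)
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= m & c0 + 1 <= m
  out <- matrix(NA_real_, nrow(r), ncol(r))
  i00 <- cbind(r0[ok], c0[ok])
  i10 <- cbind(r0[ok] + 1, c0[ok])
  i01 <- cbind(r0[ok], c0[ok] + 1)
  i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
  out[ok] <- z[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
    z[i10] * fr[ok] * (1 - fc[ok]) +
    z[i01] * (1 - fr[ok]) * fc[ok] +
    z[i11] * fr[ok] * fc[ok]
  out
}

#' Radial spectrum: amplitude sums on concentric semicircles
#'
#' Upper-half-plane off-DC pixels are binned by rounded integer radius;
#' `beta(r)` is the amplitude sum in bin `r` for `r = 1 .. M/2 - 1`.  Bins
#' beyond `M/2 - 1` (the corner region of the square spectrum) are
#' discarded.
#'
#' @param spec a [SpectrumSet]
#' @param withCounts also return per-bin pixel counts
#' @return Numeric vector `beta` of length `M/2 - 1`, or a list with
#'   elements `beta` and `counts` when `withCounts = TRUE`.
#' @export
radialSpectrum <- function(spec, withCounts = FALSE) {
  m <- spec@gridSize
  amp <- spec@amplitude
  geo <- .spectrumGeometry(m)
  rmax <- m %/% 2 - 1L
  r <- as.integer(round(sqrt(geo$kx[geo$half]^2 + geo$ky[geo$half]^2)))
  keep <- r >= 1L & r <= rmax
  beta <- numeric(rmax)
  counts <- numeric(rmax)
  sums <- rowsum(amp[geo$half][keep], r[keep])
  idx <- as.integer(rownames(sums))
  beta[idx] <- sums[, 1]
  tab <- table(r[keep])
  counts[as.integer(names(tab))] <- as.numeric(tab)
  if (withCounts) list(beta = beta, counts = counts) else beta
}

#' Texture direction index Stdi
#'
#' The ratio of the mean angular-spectrum amplitude to the amplitude of the
#' dominant direction, `mean(A) / max(A)`, in (0, 1].  Values near 0
#' indicate a strongly dominant direction; an isotropic surface gives
#' values near 1.
#'
#' @param spec a [SpectrumSet]
#' @return A single number in (0, 1], or `NA` for an all-zero spectrum.
#' @export
sTdi <- function(spec) {
  a <- spec@angular
  if (length(a) == 0 || max(a) == 0) return(NA_real_)
  mean(a) / max(a)
}

#' Radial wave index Srwi
#'
#' The ratio of the mean radial-profile amplitude to the amplitude of the
#' dominant wavelength, `mean(beta') / max(beta')`, in (0, 1].  Near 0
#' when a single wavelength dominates; near 1 when no wavelength
#' dominates.  The comparison uses the count-normalised radial profile
#' (mean amplitude per semicircle) so that all wavelengths are compared
#' on an equal footing: the raw sums `beta(r)` grow linearly with the
#' number of lattice pixels on the semicircle, which would bias the
#' dominant wavelength towards short wavelengths even for white noise.
#'
#' @param spec a [SpectrumSet]
#' @return A single number in (0, 1], or `NA` for an all-zero spectrum.
#' @export
sRwi <- function(spec) {
  b <- spec@radial
  cnt <- spec@radialCounts
  if (length(b) == 0 || max(b) == 0) return(NA_real_)
  prof <- ifelse(cnt > 0, b / pmax(cnt, 1), 0)
  ## 3-tap smoothing before the peak ratio (robust dominant-wavelength
  ## detection, see sTdi)
  n <- length(prof)
  if (n >= 3)
    prof <- (prof + prof[c(1, 1:(n - 1))] + prof[c(2:n, n)]) / 3
  mean(prof) / max(prof)
}

#' Median radius of the integral radial spectrum
#'
#' The (linearly interpolated) radius `r0.5` at which the cumulative
#' radial spectrum (the cumulative count-normalised radial profile, see
#' [amplitudeSpectrum()]) reaches half of its total, treating the
#' cumulative spectrum as piecewise linear through (0, 0), (1, betai(1)),
#' ..., (M/2-1, total).
#'
#' @param spec a [SpectrumSet]
#' @return A list with elements `radius` (r0.5, pixels) and `fraction`
#'   (the normalised cumulative spectrum interpolated at that radius,
#'   0.5 by construction).
#' @export
halfPowerRadius <- function(spec) {
  cum <- spec@integralRadial
  tot <- cum[length(cum)]
  if (tot <= 0) return(list(radius = NA_real_, fraction = NA_real_))
  r <- seq_along(cum)
  target <- 0.5 * tot
  j <- which(cum >= target)[1]
  if (j == 1L) {
    r05 <- target / cum[1]
  } else {
    r05 <- (j - 1) + (target - cum[j - 1]) / (cum[j] - cum[j - 1])
  }
  frac <- stats::approx(c(0, r), c(0, cum), xout = r05)$y / tot
  list(radius = r05, fraction = frac)
}

#' Average half wavelength Shw
#'
#' The half wavelength corresponding to the median radius of the integral
#' radial spectrum: `Shw = pitch * (M - 1) / (2 * r0.5)` nm.  A pure
#' sinusoid of wavelength lambda yields approximately lambda / 2.  Set
#' `halfFactor = FALSE` for the alternative convention without the factor
#' 2 (the full wavelength at the median radius).
#'
#' @param spec a [SpectrumSet]
#' @param pixelPitch pixel pitch, nm (default: carried by `spec`)
#' @param halfFactor logical; divide by `2 * r0.5` (default) rather than
#'   `r0.5`
#' @return Length in nm, or `NA` for an all-zero spectrum.
#' @export
sHw <- function(spec, pixelPitch = NULL, halfFactor = TRUE) {
  if (is.null(pixelPitch)) pixelPitch <- spec@pixelPitch
  hp <- halfPowerRadius(spec)
  if (is.na(hp$radius)) return(NA_real_)
  denom <- if (halfFactor) 2 * hp$radius else hp$radius
  pixelPitch * (spec@gridSize - 1) / denom
}
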