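## Cantilever calibration: deflection sensitivity from a rigid-substrate
## ramp, spring constant from the thermal-noise PSD (SHO Lorentzian fit +
## equipartition closure).

#' Welch-averaged power spectral density
#'
#' One-sided PSD estimate by Welch's method: Hann-windowed segments with
#' 50% overlap, periodograms averaged across segments.  Used by
#' [fitSpringConstantPSD()]; exported because a PSD estimate of a thermal
#' record is useful on its own.
#'
#' @param x numeric time series
#' @param fs sampling rate, Hz
#' @param segmentLength samples per segment (default 2^13)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return A data.frame with columns `freq` (Hz) and `psd`
#'   (units^2 per Hz), excluding the DC bin.
#' @export
welchPsd <- function(x, fs, segmentLength = 2^13, overlap = 0.5) {
  n <- length(x)
  segmentLength <- min(segmentLength, n)
  step <- max(1L, round(segmentLength * (1 - overlap)))
  starts <- seq(1L, n - segmentLength + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segmentLength) - 1) /
                         (segmentLength - 1))
  norm <- fs * sum(w^2)
  nf <- segmentLength %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segmentLength - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / norm
    acc <- acc + 2 * p[2:(nf + 1L)]          # one-sided, drop DC
  }
  data.frame(freq = (1:nf) * fs / segmentLength,
             psd = acc / length(starts))
}

#' Simulate a rigid-substrate deflection ramp
#'
#' A deflection-signal-versus-z record on a non-deforming substrate:
#' zero signal until the contact point, then a linear rise with slope
#' `1 / sensitivity` volts per nm.
#'
#' @param sensitivity true deflection sensitivity, nm/V
#' @param zRange z travel, nm
#' @param contactZ z position of the contact point, nm
#' @param n number of samples
#' @param noiseSd Gaussian noise sd on the deflection signal, V
#' @param seed integer seed
#' @return A data.frame with columns `z` (nm) and `deflection` (V).
#' @export
simulateRigidContact <- function(sensitivity = 50, zRange = 500,
                                 contactZ = 200, n = 500, noiseSd = 0,
                                 seed = 1) {
  z <- seq(0, zRange, length.out = n)
  v <- pmax(0, z - contactZ) / sensitivity
  if (noiseSd > 0)
    v <- v + withSeed(seed, stats::rnorm(n, sd = noiseSd))
  data.frame(z = z, deflection = v)
}

#' Fit the optical-lever deflection sensitivity
#'
#' Recovers the deflection sensitivity (nm/V) from a contact ramp on a
#' rigid substrate: local slopes of the deflection signal against z are
#' computed, the contact region is identified as the longest run whose
#' local slope lies within 10% of the median contact slope, and the
#' sensitivity is the least-squares slope of z against signal over that
#' run.
#'
#' Local slopes are computed over a lag of about 1/50 of the record (which
#' averages measurement noise); under noise the 10% tolerance is widened to
#' the local slope-noise floor so the contact run is not fragmented.
#'
#' @param ramp data.frame with columns `z` (nm) and `deflection` (V), as
#'   returned by [simulateRigidContact()]
#' @return Deflection sensitivity, nm/V.
#' @export
fitDeflectionSensitivity <- function(ramp) {
  z <- ramp$z
  v <- ramp$deflection
  n <- length(z)
  if (n < 20) stop("ramp too short")
  ptNoise <- stats::mad(diff(v)) / sqrt(2)
  if (diff(range(v)) <= max(8 * ptNoise, 1e-12))
    stop("no contact region found in the ramp")
  lag <- max(3L, round(n / 10))
  i0 <- seq_len(n - lag)
  ds <- (v[i0 + lag] - v[i0]) / (z[i0 + lag] - z[i0])
  scale <- max(abs(ds))
  slopeNoise <- ptNoise * sqrt(2) / (lag * mean(diff(z)))
  cand <- which(abs(ds) > 0.5 * scale)
  if (length(cand) < 5) stop("no contact region found in the ramp")
  medSlope <- stats::median(ds[cand])
  tol <- max(0.1 * abs(medSlope), 3 * slopeNoise)
  ok <- abs(ds - medSlope) <= tol
  r <- rle(ok)
  if (!any(r$values)) stop("no stable contact segment found")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  ## the longest near-median run anchors the contact segment; fit over
  ## the whole candidate contact interval, excluding samples whose lag
  ## window spans the contact-point kink
  idx <- min(min(cand) + lag, max(cand)):max(cand)
  if (length(idx) < 5) idx <- starts[best]:min(n, ends[best] + lag)
  ## regress the (noisy) signal on the noise-free z and invert the slope,
  ## avoiding regression-dilution bias
  fit <- stats::lm.fit(cbind(1, z[idx]), v[idx])
  1 / as.numeric(fit$coefficients[2])
}

## SHO Lorentzian shape, unit plateau at f = 0.
.shoShape <- function(f, f0, q) {
  f0^4 / ((f0^2 - f^2)^2 + (f0 * f / q)^2)
}

#' Calibrate the spring constant from a thermal deflection record
#'
#' Computes the Welch-averaged PSD of a free (non-contact) thermal
#' deflection record, fits an SHO Lorentzian plus white baseline in log
#' space, integrates the fitted SHO component to obtain the thermal
#' displacement variance, and closes with equipartition:
#' `k = kB * T / <z^2>`.  The fitted resonance frequency and quality
#' factor are returned alongside.
#'
#' @param trace a [ForceTrace] deflection record in nm (e.g. from
#'   [generateThermalTrace()])
#' @param temperature temperature, K (default 295)
#' @param segmentLength Welch segment length (default 2^13)
#' @return A [CalibrationResult].
#' @examples
#' th <- generateThermalTrace(ringingConfig(), 295, 0.04, seed = 1)
#' fitSpringConstantPSD(th)
#' @export
fitSpringConstantPSD <- function(trace, temperature = 295,
                                 segmentLength = 2^13) {
  stopifnot(is(trace, "ForceTrace"))
  if (temperature <= 0) stop("temperature must be > 0 K")
  fs <- samplingRate(trace)
  psd <- welchPsd(traceForce(trace), fs, segmentLength = segmentLength)
  peakIdx <- which.max(psd$psd)
  peak <- psd$psd[peakIdx]
  base <- stats::median(psd$psd)
  if (peak < 10 * base)
    stop("thermal resonance peak not resolvable above the baseline")
  f0Init <- psd$freq[peakIdx]
  halfIdx <- which(psd$psd > peak / 2)
  widthInit <- max(diff(range(psd$freq[halfIdx])), psd$freq[2] - psd$freq[1])
  qInit <- clamp(f0Init / widthInit, 1, 1e4)
  aInit <- peak / qInit^2                       # plateau of the SHO shape
  df <- data.frame(f = psd$freq, y = log(psd$psd))
  fit <- minpack.lm::nlsLM(
    y ~ log(a * .shoShape(f, f0, q) + b),
    data = df,
    start = list(a = aInit, f0 = f0Init, q = qInit,
                 b = max(base, 1e-300)),
    lower = c(0, psd$freq[1], 0.55, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((df$y - mean(df$y))^2)
  ## closed form: integral of the unit-plateau SHO shape over (0, Inf)
  ## equals pi * Q * f0 / 2
  zsq <- cf[["a"]] * pi * cf[["q"]] * cf[["f0"]] / 2   # nm^2
  k <- .kB * temperature / (zsq * 1e-18)
  new("CalibrationResult",
      deflectionSensitivity = NA_real_,
      springConstant = as.numeric(k),
      fitQuality = clamp(r2, 0, 1),
      resonanceFreq = as.numeric(cf["f0"]),
      qFactor = as.numeric(cf["q"]),
      temperature = temperature)
}

#' Write / read a calibration report as flat key-value text
#'
#' @param result a [CalibrationResult]
#' @param path output file path
#' @return `writeCalibrationReport` returns `path` invisibly;
#'   `readCalibrationReport` returns a [CalibrationResult].
#' @export
writeCalibrationReport <- function(result, path) {
  stopifnot(is(result, "CalibrationResult"))
  lines <- c(
    sprintf("deflection_sensitivity_nm_per_V = %.10g",
            result@deflectionSensitivity),
    sprintf("spring_constant_N_per_m = %.10g", result@springConstant),
    sprintf("fit_quality = %.10g", result@fitQuality),
    sprintf("resonance_freq_Hz = %.10g", result@resonanceFreq),
    sprintf("q_factor = %.10g", result@qFactor),
    sprintf("temperature_K = %.10g", result@temperature))
  writeLines(lines, path)
  invisible(path)
}

#' @param path file written by `writeCalibrationReport`
#' @rdname writeCalibrationReport
#' @export
readCalibrationReport <- function(path) {
  kv <- utils::read.table(path, sep = "=", strip.white = TRUE,
                          col.names = c("key", "value"))
  val <- stats::setNames(as.numeric(kv$value), kv$key)
  new("CalibrationResult",
      deflectionSensitivity = val[["deflection_sensitivity_nm_per_V"]],
      springConstant = val[["spring_constant_N_per_m"]],
      fitQuality = val[["fit_quality"]],
      resonanceFreq = val[["resonance_freq_Hz"]],
      qFactor = val[["q_factor"]],
      temperature = val[["temperature_K"]])
}
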