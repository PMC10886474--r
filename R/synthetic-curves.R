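## Synthetic sub-resonance force cycles and thermal cantilever noise.

#' Generate one synthetic Ringing-mode force cycle
#'
#' Builds a full approach-retract-ringing cycle for one pixel: a flat
#' baseline (region A), linear contact loading to the maximum load (B-C),
#' a linear retract through the adhesion well down to `-adhesionForce`
#' (point D), an instantaneous detachment, and the post-detachment ringing
#' (region F): a damped cosine
#' `-Frest * exp(-(t - td)/tau) * cos(2 pi f0 (t - td))` with
#' `tau = Q / (pi f0)`, so that the force at the detachment instant equals
#' the restored adhesion force (point E).  Gaussian force noise of sd
#' `noiseSd` is added throughout.
#'
#' @param config a [RingingConfig]
#' @param scenario a [ContactScenario]
#' @param seed integer seed for the noise
#' @return A [ForceTrace]; `groundTruth(trace)` carries the exact feature
#'   values and segment boundaries used to build the trace.
#' @examples
#' tr <- generateForceCurve(ringingConfig(), contactScenario(), seed = 1)
#' groundTruth(tr)$restoredAdhesion
#' @export
generateForceCurve <- function(config, scenario, seed = 1) {
  stopifnot(is(config, "RingingConfig"), is(scenario, "ContactScenario"))
  validObject(config); validObject(scenario)
  fs <- config@samplingRate
  f0 <- config@resonanceFreq
  q <- config@qualityFactor
  dt <- 1 / fs
  ## force loading rate, nN/s: contact stiffness (N/m == nN/nm) x speed
  rate <- scenario@contactStiffness * scenario@approachSpeed
  nBase <- max(32L, round(1.5e-4 * fs))
  nLoad <- max(8L, round(scenario@maxLoad / rate * fs))
  nRetract <- max(8L, round((scenario@maxLoad + scenario@adhesionForce) /
                              rate * fs))
  tau <- q / (pi * f0)
  nRing <- max(32L, round(5 * tau * fs))
  n <- nBase + nLoad + nRetract + nRing
  tt <- (seq_len(n) - 1) * dt
  force <- numeric(n)
  iLoad <- nBase + seq_len(nLoad)
  force[iLoad] <- scenario@maxLoad * seq_len(nLoad) / nLoad
  iRetract <- nBase + nLoad + seq_len(nRetract)
  force[iRetract] <- scenario@maxLoad -
    (scenario@maxLoad + scenario@adhesionForce) * seq_len(nRetract) /
    nRetract
  iRing <- nBase + nLoad + nRetract + seq_len(nRing)
  detachIdx <- nBase + nLoad + nRetract          # last retract sample (D)
  td <- tt[detachIdx + 1L]                       # first ringing sample
  if (scenario@restoredForce > 0) {
    dtau <- tt[iRing] - td
    force[iRing] <- -scenario@restoredForce * exp(-dtau / tau) *
      cos(2 * pi * f0 * dtau)
  }
  if (scenario@noiseSd > 0)
    force <- force + withSeed(seed, stats::rnorm(n, sd = scenario@noiseSd))
  truth <- list(
    adhesion = scenario@adhesionForce,
    restoredAdhesion = scenario@restoredForce,
    viscoelasticAdhesion = scenario@adhesionForce - scenario@restoredForce,
    maxLoad = scenario@maxLoad,
    deformation = scenario@maxLoad / scenario@contactStiffness,  # nm
    detachmentTime = td,
    detachmentIndex = detachIdx,
    segments = list(baseline = c(1L, nBase),
                    loading = c(nBase + 1L, nBase + nLoad),
                    retract = c(nBase + nLoad + 1L, detachIdx),
                    ringing = c(detachIdx + 1L, n)),
    config = config, scenario = scenario, seed = seed)
  forceTrace(tt, force, units = "nN", channel = "force",
             metadata = list(truth = truth))
}

#' Generate a thermally driven cantilever deflection record
#'
#' Synthesises the free (non-contact) deflection of a simple harmonic
#' oscillator driven by white thermal noise: the spectrum follows the SHO
#' Lorentzian with the configured resonance frequency and quality factor
#' and the total variance obeys equipartition,
#' `<z^2> = kB * T / k` (deflection in nm).  Synthesis is performed in the
#' frequency domain (complex Gaussian amplitudes shaped by the SHO
#' response), so the expected variance is exact and the sample variance
#' fluctuates as it would for a physical record of finite length.
#'
#' @param config a [RingingConfig]
#' @param temperature temperature, K (strictly negative values are
#'   rejected; 0 K gives the zero trace)
#' @param duration record duration, s; `duration * samplingRate` must be
#'   at least 2^16 samples
#' @param seed integer seed
#' @return A [ForceTrace] with `channel = "deflection"` and units nm.
#' @examples
#' th <- generateThermalTrace(ringingConfig(), 295, duration = 0.04,
#'                            seed = 1)
#' var(traceForce(th)) # approx kB * 295 / 0.4 * 1e18 nm^2
#' @export
generateThermalTrace <- function(config, temperature = 295, duration,
                                 seed = 1) {
  stopifnot(is(config, "RingingConfig"))
  validObject(config)
  if (temperature < 0) stop("temperature must be >= 0 K")
  fs <- config@samplingRate
  n <- round(duration * fs)
  if (n < 2^16)
    stop("duration x samplingRate must be at least 2^16 samples")
  tt <- (seq_len(n) - 1) / fs
  if (temperature == 0)
    return(forceTrace(tt, numeric(n), units = "nm",
                      channel = "deflection",
                      metadata = list(truth = list(config = config,
                                                   temperature = 0))))
  f0 <- config@resonanceFreq
  q <- config@qualityFactor
  k <- config@springConstant
  varTarget <- .kB * temperature / k * 1e18     # nm^2
  freqs <- (0:(n %/% 2)) * fs / n
  g <- f0^4 / ((f0^2 - freqs^2)^2 + (f0 * freqs / q)^2)
  g[1] <- 0                                     # no DC power
  z <- withSeed(seed, {
    nf <- length(freqs)
    re <- stats::rnorm(nf); im <- stats::rnorm(nf)
    spec <- complex(real = re, imaginary = im) * sqrt(g / 2)
    spec[1] <- 0
    spec[nf] <- complex(real = re[nf] * sqrt(g[nf]), imaginary = 0)
    full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
    Re(stats::fft(full, inverse = TRUE)) / n
  })
  ## scale so that E[var] = kB T / k exactly on the discrete grid
  expVar <- (2 * sum(g[2:(length(g) - 1)]) + g[length(g)]) / n^2
  z <- z * sqrt(varTarget / expVar)
  forceTrace(tt, z, units = "nm", channel = "deflection",
             metadata = list(truth = list(
               config = config, temperature = temperature,
               varianceTarget = varTarget, seed = seed)))
}

#' Simulate a grid of force cycles over a known adhesion pattern
#'
#' Convenience generator for testing the map-assembly stage: one force
#' cycle per pixel, with per-pixel adhesion given by `pattern` (nN) and
#' restored adhesion `restoredRatio * pattern`.
#'
#' @param pattern square numeric matrix of adhesion forces, nN
#' @param config a [RingingConfig]
#' @param scenario base [ContactScenario]; its adhesion/restored values
#'   are overridden per pixel
#' @param restoredRatio restored / adhesion ratio per pixel
#' @param seed integer seed
#' @return A list-matrix (with `dim`) of [ForceTrace] objects.
#' @export
simulateForceGrid <- function(pattern, config = ringingConfig(),
                              scenario = contactScenario(),
                              restoredRatio = 0.75, seed = 1) {
  stopifnot(is.matrix(pattern))
  out <- vector("list", length(pattern))
  dim(out) <- dim(pattern)
  for (i in seq_len(nrow(pattern))) {
    for (j in seq_len(ncol(pattern))) {
      sc <- scenario
      sc@adhesionForce <- pattern[i, j]
      sc@restoredForce <- restoredRatio * pattern[i, j]
      validObject(sc)
      out[[i, j]] <- generateForceCurve(config, sc,
                                        seed = deriveSeed(seed, i, j))
    }
  }
  out
}
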