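#' @import methods
NULL

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Cantilever and acquisition configuration
#'
#' Holds the probe properties needed to simulate and analyse Ringing-mode
#' force cycles: spring constant (N/m), fundamental resonance frequency (Hz),
#' quality factor, sampling rate (Hz) and optical-lever deflection
#' sensitivity (nm/V).  The sampling rate must be at least ten times the
#' resonance frequency so that the post-detachment ringing is resolvable.
#'
#' @slot springConstant cantilever stiffness, N/m
#' @slot resonanceFreq fundamental resonance frequency, Hz
#' @slot qualityFactor dimensionless quality factor of the resonance
#' @slot samplingRate acquisition sampling rate, Hz
#' @slot deflectionSensitivity optical lever sensitivity, nm/V
#' @aliases RingingConfig
#' @exportClass RingingConfig
setClass("RingingConfig",
  representation(
    springConstant = "numeric",
    resonanceFreq = "numeric",
    qualityFactor = "numeric",
    samplingRate = "numeric",
    deflectionSensitivity = "numeric"
  )
)

setValidity("RingingConfig", function(object) {
  v <- c(object@springConstant, object@resonanceFreq, object@qualityFactor,
         object@samplingRate, object@deflectionSensitivity)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all configuration values must be finite and strictly positive")
  if (object@samplingRate < 10 * object@resonanceFreq)
    return(sprintf(
      "samplingRate (%.3g Hz) must be >= 10 x resonanceFreq (%.3g Hz): the ringing signal would not be resolvable",
      object@samplingRate, object@resonanceFreq))
  TRUE
})

#' @param springConstant cantilever stiffness, N/m
#' @param resonanceFreq resonance frequency, Hz
#' @param qualityFactor quality factor (dimensionless)
#' @param samplingRate sampling rate, Hz
#' @param deflectionSensitivity deflection sensitivity, nm/V
#' @return A `RingingConfig` object.
#' @examples
#' ringingConfig()
#' @rdname RingingConfig-class
#' @export
ringingConfig <- function(springConstant = 0.4, resonanceFreq = 75e3,
                          qualityFactor = 25, samplingRate = 2e6,
                          deflectionSensitivity = 50) {
  new("RingingConfig", springConstant = springConstant,
      resonanceFreq = resonanceFreq, qualityFactor = qualityFactor,
      samplingRate = samplingRate,
      deflectionSensitivity = deflectionSensitivity)
}

#' Single-pixel probe-sample contact scenario
#'
#' Ground-truth description of one force cycle: the adhesion force (the
#' retract minimum, point D of the cycle), the restored adhesion force (the
#' force at complete detachment, point E), the maximum load, the linearised
#' contact stiffness, the approach/retract speed and the measurement noise.
#'
#' @slot adhesionForce adhesion force magnitude at point D, nN
#' @slot restoredForce restored adhesion force at point E, nN
#' @slot maxLoad maximum load force, nN
#' @slot contactStiffness linearised contact stiffness, N/m
#' @slot approachSpeed piezo approach/retract speed, nm/s
#' @slot noiseSd Gaussian force-noise standard deviation, nN
#' @aliases ContactScenario
#' @exportClass ContactScenario
setClass("ContactScenario",
  representation(
    adhesionForce = "numeric",
    restoredForce = "numeric",
    maxLoad = "numeric",
    contactStiffness = "numeric",
    approachSpeed = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("ContactScenario", function(object) {
  if (object@adhesionForce < 0)
    return("adhesionForce must be >= 0")
  if (object@restoredForce < 0 || object@restoredForce > object@adhesionForce)
    return("restoredForce must satisfy 0 <= restoredForce <= adhesionForce")
  if (object@maxLoad <= 0) return("maxLoad must be > 0")
  if (object@contactStiffness <= 0) return("contactStiffness must be > 0")
  if (object@approachSpeed <= 0) return("approachSpeed must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param adhesionForce adhesion force (point D), nN
#' @param restoredForce restored adhesion force (point E), nN
#' @param maxLoad maximum load force, nN
#' @param contactStiffness linearised contact stiffness, N/m
#' @param approachSpeed piezo speed, nm/s
#' @param noiseSd force noise sd, nN
#' @return A `ContactScenario` object.
#' @examples
#' contactScenario(adhesionForce = 2, restoredForce = 1.5)
#' @rdname ContactScenario-class
#' @export
contactScenario <- function(adhesionForce = 2, restoredForce = 1.5,
                            maxLoad = 2, contactStiffness = 0.01,
                            approachSpeed = 3e5, noiseSd = 0) {
  new("ContactScenario", adhesionForce = adhesionForce,
      restoredForce = restoredForce, maxLoad = maxLoad,
      contactStiffness = contactStiffness, approachSpeed = approachSpeed,
      noiseSd = noiseSd)
}

#' Synthetic cell-surface generator configuration
#'
#' Parameters of the fold + grain surface model.  A resting-cell surface is
#' dominated by an oriented long-wavelength membrane fold field; activation
#' replaces it with an isotropic granular field while the overall RMS
#' amplitude is pinned to `targetRms` so that only the spatial organisation
#' of the surface changes with the activation level.
#'
#' @slot gridSize image size in pixels (even, >= 32)
#' @slot pixelPitch pixel pitch, nm
#' @slot activationLevel latent activation level in \[0, 1\]
#' @slot grainRadius Gaussian grain radius (sigma), nm
#' @slot grainDensity grain density at full activation, grains per um^2
#' @slot foldWavelength dominant membrane-fold wavelength, nm
#' @slot foldAnisotropy orientation strength of the fold field in \[0, 1\]
#' @slot foldDirection dominant fold wave-vector direction, radians
#' @slot planeTilt length-2 plane gradient (d value / d nm) in x and y
#' @slot targetRms RMS amplitude the construction is rescaled to, channel units
#' @slot noiseSd white pixel noise sd relative to unit-RMS structure
#' @aliases SurfaceConfig
#' @exportClass SurfaceConfig
setClass("SurfaceConfig",
  representation(
    gridSize = "integer",
    pixelPitch = "numeric",
    activationLevel = "numeric",
    grainRadius = "numeric",
    grainDensity = "numeric",
    foldWavelength = "numeric",
    foldAnisotropy = "numeric",
    foldDirection = "numeric",
    planeTilt = "numeric",
    targetRms = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("SurfaceConfig", function(object) {
  m <- object@gridSize
  if (length(m) != 1L || is.na(m) || m < 32L || m %% 2L != 0L)
    return("gridSize must be a single even integer >= 32")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@activationLevel < 0 || object@activationLevel > 1)
    return("activationLevel must lie in [0, 1]")
  if (object@grainRadius < object@pixelPitch)
    return(sprintf(
      "grainRadius (%.3g nm) must be >= pixelPitch (%.3g nm): grains would be unresolvable",
      object@grainRadius, object@pixelPitch))
  if (object@grainDensity <= 0) return("grainDensity must be > 0")
  if (object@foldWavelength <= 2 * object@pixelPitch)
    return("foldWavelength must exceed 2 x pixelPitch")
  if (object@foldAnisotropy < 0 || object@foldAnisotropy > 1)
    return("foldAnisotropy must lie in [0, 1]")
  if (length(object@planeTilt) != 2L || any(!is.finite(object@planeTilt)))
    return("planeTilt must be a finite length-2 vector")
  if (object@targetRms <= 0) return("targetRms must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param gridSize image size in pixels
#' @param pixelPitch pixel pitch, nm
#' @param activationLevel activation level in \[0, 1\]
#' @param grainRadius grain sigma, nm
#' @param grainDensity grains per um^2 at full activation
#' @param foldWavelength fold wavelength, nm
#' @param foldAnisotropy fold orientation strength in \[0, 1\]
#' @param foldDirection fold direction, radians
#' @param planeTilt length-2 plane gradient per nm
#' @param targetRms target RMS amplitude, channel units
#' @param noiseSd white-noise sd relative to unit-RMS structure
#' @return A `SurfaceConfig` object.
#' @examples
#' surfaceConfig(activationLevel = 0.5)
#' @rdname SurfaceConfig-class
#' @export
surfaceConfig <- function(gridSize = 256L, pixelPitch = 20,
                          activationLevel = 0, grainRadius = 55,
                          grainDensity = 120, foldWavelength = 420,
                          foldAnisotropy = 0.7, foldDirection = 0,
                          planeTilt = c(0, 0), targetRms = 1,
                          noiseSd = 0.25) {
  new("SurfaceConfig", gridSize = as.integer(gridSize),
      pixelPitch = pixelPitch, activationLevel = activationLevel,
      grainRadius = grainRadius, grainDensity = grainDensity,
      foldWavelength = foldWavelength, foldAnisotropy = foldAnisotropy,
      foldDirection = foldDirection, planeTilt = as.numeric(planeTilt),
      targetRms = targetRms, noiseSd = noiseSd)
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' A time-sampled force (or deflection) trace
#'
#' One pixel's approach-retract-ringing cycle, or a thermal cantilever
#' deflection record.  Time must be uniformly sampled and strictly
#' increasing.  `metadata` carries the generating configuration and, for
#' synthetic traces, the ground truth features.
#'
#' @slot time sample times, s
#' @slot force force (nN) or deflection (nm) samples
#' @slot units units of the `force` slot, `"nN"` or `"nm"`
#' @slot channel `"force"` or `"deflection"`
#' @slot metadata list of provenance information (config, ground truth)
#' @aliases ForceTrace
#' @exportClass ForceTrace
setClass("ForceTrace",
  representation(
    time = "numeric",
    force = "numeric",
    units = "character",
    channel = "character",
    metadata = "list"
  ),
  prototype(units = "nN", channel = "force", metadata = list())
)

setValidity("ForceTrace", function(object) {
  n <- length(object@time)
  if (n < 2L) return("a trace needs at least two samples")
  if (length(object@force) != n)
    return("time and force must have equal length")
  dt <- diff(object@time)
  if (any(dt <= 0)) return("time must be strictly increasing")
  if ((max(dt) - min(dt)) > 1e-9 * mean(dt) * n)
    return("time must be uniformly sampled (relative step tolerance 1e-9)")
  TRUE
})

#' @param time sample times, s
#' @param force samples (nN force or nm deflection)
#' @param units units string
#' @param channel channel label
#' @param metadata provenance list
#' @return A `ForceTrace` object.
#' @rdname ForceTrace-class
#' @export
forceTrace <- function(time, force, units = "nN", channel = "force",
                       metadata = list()) {
  new("ForceTrace", time = as.numeric(time), force = as.numeric(force),
      units = units, channel = channel, metadata = metadata)
}

#' A square surface map of one data channel
#'
#' An M x M grid of channel values (height in nm, or an adhesion channel in
#' nN treated downstream as "effective height") with its pixel pitch and
#' provenance.
#'
#' @slot values M x M numeric matrix of channel values
#' @slot pixelPitch pixel pitch, nm
#' @slot channel channel label, e.g. `"height"` or `"restored adhesion"`
#' @slot units channel units, e.g. `"nm"` or `"nN"`
#' @slot provenance free-form source identifier
#' @slot metadata list of generator ground truth / processing history
#' @aliases SurfaceMap
#' @exportClass SurfaceMap
setClass("SurfaceMap",
  representation(
    values = "matrix",
    pixelPitch = "numeric",
    channel = "character",
    units = "character",
    provenance = "character",
    metadata = "list"
  ),
  prototype(channel = "height", units = "nm", provenance = "",
            metadata = list())
)

setValidity("SurfaceMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != ncol(v)) return("the map must be square")
  if (nrow(v) %% 2L != 0L) return("the grid size must be even")
  if (any(!is.finite(v))) return("all map values must be finite")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number")
  TRUE
})

#' @param values square numeric matrix
#' @param pixelPitch pixel pitch, nm
#' @param channel channel label
#' @param units channel units
#' @param provenance source id
#' @param metadata provenance list
#' @return A `SurfaceMap` object.
#' @examples
#' surfaceMap(matrix(rnorm(64^2), 64), pixelPitch = 20)
#' @rdname SurfaceMap-class
#' @export
surfaceMap <- function(values, pixelPitch, channel = "height",
                       units = "nm", provenance = "", metadata = list()) {
  new("SurfaceMap", values = values, pixelPitch = pixelPitch,
      channel = channel, units = units, provenance = provenance,
      metadata = metadata)
}

#' DC-centred 2D amplitude spectrum with angular and radial reductions
#'
#' The modulus of the 2D DFT of a mean-subtracted map, quadrant-swapped so
#' the DC bin sits at the centre pixel, together with the angular spectrum
#' A(i) (amplitude sums along equiangular half-plane lines), the radial
#' spectrum beta(r) (amplitude sums on concentric semicircles, r = 1 ..
#' M/2 - 1) and its cumulative (integral) form.
#'
#' @slot amplitude DC-centred M x M amplitude matrix
#' @slot angular angular spectrum A(i), one value per line
#' @slot radial radial spectrum beta(r), r = 1 .. M/2 - 1
#' @slot integralRadial cumulative sums of `radial`
#' @slot radialCounts number of half-plane pixels contributing to each radius
#' @slot gridSize image size M, pixels
#' @slot pixelPitch pixel pitch, nm
#' @slot nLines number of angular lines used for `angular`
#' @aliases SpectrumSet
#' @exportClass SpectrumSet
setClass("SpectrumSet",
  representation(
    amplitude = "matrix",
    angular = "numeric",
    radial = "numeric",
    integralRadial = "numeric",
    radialCounts = "numeric",
    gridSize = "integer",
    pixelPitch = "numeric",
    nLines = "integer"
  )
)

setValidity("SpectrumSet", function(object) {
  if (any(object@amplitude < 0)) return("amplitudes must be >= 0")
  if (any(object@angular < 0) || any(object@radial < 0))
    return("angular and radial amplitudes must be >= 0")
  if (is.unsorted(object@integralRadial))
    return("the integral radial spectrum must be non-decreasing")
  TRUE
})

#' Cantilever calibration result
#'
#' @slot deflectionSensitivity nm/V (NA when not part of the calibration)
#' @slot springConstant N/m
#' @slot fitQuality coefficient of determination of the PSD fit, in \[0, 1\]
#' @slot resonanceFreq fitted resonance frequency, Hz
#' @slot qFactor fitted quality factor
#' @slot temperature temperature assumed for equipartition, K
#' @aliases CalibrationResult
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(
    deflectionSensitivity = "numeric",
    springConstant = "numeric",
    fitQuality = "numeric",
    resonanceFreq = "numeric",
    qFactor = "numeric",
    temperature = "numeric"
  )
)

setValidity("CalibrationResult", function(object) {
  if (!is.na(object@springConstant) && object@springConstant <= 0)
    return("springConstant must be > 0")
  if (!is.na(object@fitQuality) &&
      (object@fitQuality < 0 || object@fitQuality > 1))
    return("fitQuality must lie in [0, 1]")
  TRUE
})

#' Map quality-control report
#'
#' Automated proxies for the visual artifact screening of scan images:
#' a line-artifact score (largest adjacent-row median jump relative to the
#' map RMS), the fraction of spike pixels (beyond 6 x MAD) and the fraction
#' of saturated pixels (at the extreme representable values).
#'
#' @slot lineArtifactScore dimensionless
#' @slot spikeFraction in \[0, 1\]
#' @slot saturationFraction in \[0, 1\]
#' @slot passed logical, TRUE when all scores are below their thresholds
#' @slot thresholds the thresholds the scores were compared against
#' @aliases QCReport
#' @exportClass QCReport
setClass("QCReport",
  representation(
    lineArtifactScore = "numeric",
    spikeFraction = "numeric",
    saturationFraction = "numeric",
    passed = "logical",
    thresholds = "list"
  )
)

setValidity("QCReport", function(object) {
  f <- c(object@spikeFraction, object@saturationFraction)
  if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  TRUE
})

#' A synthetic activation time-course of surface maps
#'
#' A manifest (group, activation time, cell id, channel, latent activation
#' level) plus the generated maps, one `SurfaceMap` per manifest row.
#' Groups are the two controls (`CTR 0m`, `CTR 120m`, level 0) and one
#' `ACT <t>m` group per activation time.
#'
#' @slot manifest data.frame with columns mapId, group, timeMin, cellId,
#'   channel, activationLevel
#' @slot maps named list of `SurfaceMap` objects, names matching
#'   `manifest$mapId`
#' @aliases ActivationSeries
#' @exportClass ActivationSeries
setClass("ActivationSeries",
  representation(manifest = "data.frame", maps = "list")
)

setValidity("ActivationSeries", function(object) {
  need <- c("mapId", "group", "timeMin", "cellId", "channel",
            "activationLevel")
  if (!all(need %in% names(object@manifest)))
    return(paste("manifest must have columns", paste(need, collapse = ", ")))
  if (!identical(sort(names(object@maps)),
                 sort(as.character(object@manifest$mapId))))
    return("map names must match manifest mapId")
  TRUE
})

#' Monotone calibration of spatial parameters against activation level
#'
#' Isotonic (monotone) regressions of selected restored-adhesion-channel
#' parameters against the latent activation level, with bootstrap
#' replicates for interval estimation, used by [estimateActivation()].
#'
#' @slot parameters parameter names used (default Srwi and Shw)
#' @slot channel channel the calibration was fitted on
#' @slot curves per-parameter list(level, fitted) monotone curves
#' @slot bootCurves list of bootstrap replicate curve sets
#' @slot residSd per-parameter residual standard deviation
#' @slot tau saturation constant (min) mapping level to activation time
#' @aliases ActivationCalibration
#' @exportClass ActivationCalibration
setClass("ActivationCalibration",
  representation(
    parameters = "character",
    channel = "character",
    curves = "list",
    bootCurves = "list",
    residSd = "numeric",
    tau = "numeric"
  )
)
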