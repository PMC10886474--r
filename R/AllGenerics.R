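#' Accessors for afmring data classes
#'
#' Small accessor generics following Bioconductor conventions: slot access
#' goes through these rather than `@`.
#'
#' @param object an afmring object
#' @return The corresponding slot value.
#' @name afmring-accessors
NULL

#' @rdname afmring-accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname afmring-accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname afmring-accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @rdname afmring-accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname afmring-accessors
#' @export
setGeneric("traceForce", function(object) standardGeneric("traceForce"))

#' @rdname afmring-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname afmring-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname afmring-accessors
#' @export
setGeneric("angularAmplitudes",
           function(object) standardGeneric("angularAmplitudes"))

#' @rdname afmring-accessors
#' @export
setGeneric("radialAmplitudes",
           function(object) standardGeneric("radialAmplitudes"))

#' @rdname afmring-accessors
#' @export
setGeneric("integralRadial",
           function(object) standardGeneric("integralRadial"))

#' @rdname afmring-accessors
#' @export
setGeneric("amplitude2d", function(object) standardGeneric("amplitude2d"))

#' @rdname afmring-accessors
#' @export
setGeneric("seriesManifest",
           function(object) standardGeneric("seriesManifest"))

#' @rdname afmring-accessors
#' @export
setGeneric("seriesMaps", function(object) standardGeneric("seriesMaps"))

setMethod("mapValues", "SurfaceMap", function(object) object@values)
setMethod("pixelPitch", "SurfaceMap", function(object) object@pixelPitch)
setMethod("pixelPitch", "SpectrumSet", function(object) object@pixelPitch)
setMethod("channelName", "SurfaceMap", function(object) object@channel)
setMethod("channelName", "ForceTrace", function(object) object@channel)
setMethod("traceTime", "ForceTrace", function(object) object@time)
setMethod("traceForce", "ForceTrace", function(object) object@force)
setMethod("samplingRate", "ForceTrace", function(object)
  1 / mean(diff(object@time)))
setMethod("samplingRate", "RingingConfig", function(object)
  object@samplingRate)
setMethod("groundTruth", "ForceTrace", function(object)
  object@metadata$truth)
setMethod("groundTruth", "SurfaceMap", function(object)
  object@metadata$truth)
setMethod("angularAmplitudes", "SpectrumSet", function(object)
  object@angular)
setMethod("radialAmplitudes", "SpectrumSet", function(object)
  object@radial)
setMethod("integralRadial", "SpectrumSet", function(object)
  object@integralRadial)
setMethod("amplitude2d", "SpectrumSet", function(object) object@amplitude)
setMethod("seriesManifest", "ActivationSeries", function(object)
  object@manifest)
setMethod("seriesMaps", "ActivationSeries", function(object) object@maps)

#' @rdname afmring-accessors
#' @export
setMethod("dim", "SurfaceMap", function(x) dim(x@values))

#' @rdname afmring-accessors
#' @export
setMethod("length", "ForceTrace", function(x) length(x@force))

setMethod("show", "RingingConfig", function(object) {
  cat("RingingConfig: k =", object@springConstant, "N/m, f0 =",
      object@resonanceFreq / 1e3, "kHz, Q =", object@qualityFactor,
      ", fs =", object@samplingRate / 1e6, "MHz, sens =",
      object@deflectionSensitivity, "nm/V\n")
})

setMethod("show", "ContactScenario", function(object) {
  cat(sprintf(
    "ContactScenario: Fadh = %.3g nN, Frest = %.3g nN, Fmax = %.3g nN, kc = %.3g N/m, noise = %.3g nN\n",
    object@adhesionForce, object@restoredForce, object@maxLoad,
    object@contactStiffness, object@noiseSd))
})

setMethod("show", "SurfaceConfig", function(object) {
  cat(sprintf(
    "SurfaceConfig: %d x %d px at %.3g nm/px, activation %.2f\n",
    object@gridSize, object@gridSize, object@pixelPitch,
    object@activationLevel))
  cat(sprintf(
    "  folds: lambda = %.3g nm, anisotropy %.2f; grains: sigma = %.3g nm, density %.3g/um^2; RMS %.3g\n",
    object@foldWavelength, object@foldAnisotropy, object@grainRadius,
    object@grainDensity, object@targetRms))
})

setMethod("show", "ForceTrace", function(object) {
  n <- length(object@force)
  cat(sprintf("ForceTrace (%s): %d samples at %.3g MHz, %.3g ms span [%s]\n",
              object@channel, n, samplingRate(object) / 1e6,
              1e3 * (object@time[n] - object@time[1]), object@units))
})

setMethod("show", "SurfaceMap", function(object) {
  m <- nrow(object@values)
  cat(sprintf(
    "SurfaceMap '%s': %d x %d px, %.3g nm/px (%.2f x %.2f um), Sq = %.3g %s\n",
    object@channel, m, m, object@pixelPitch,
    m * object@pixelPitch / 1e3, m * object@pixelPitch / 1e3,
    rmsAboutMean(object@values), object@units))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf(
    "SpectrumSet: %d x %d DC-centred amplitudes, %d angular lines, %d radii\n",
    object@gridSize, object@gridSize, object@nLines,
    length(object@radial)))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: k = %.4g N/m, f0 = %.4g kHz, Q = %.3g, R^2 = %.3f (T = %g K)\n",
    object@springConstant, object@resonanceFreq / 1e3, object@qFactor,
    object@fitQuality, object@temperature))
  if (!is.na(object@deflectionSensitivity))
    cat(sprintf("  deflection sensitivity: %.4g nm/V\n",
                object@deflectionSensitivity))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf(
    "QCReport: line %.3g, spikes %.4f, saturation %.5f -> %s\n",
    object@lineArtifactScore, object@spikeFraction,
    object@saturationFraction, if (object@passed) "PASSED" else "FAILED"))
})

setMethod("show", "ActivationSeries", function(object) {
  m <- object@manifest
  cat(sprintf(
    "ActivationSeries: %d maps, %d groups (%s), %d cells, channels: %s\n",
    nrow(m), length(unique(m$group)),
    paste(unique(m$group), collapse = ", "),
    length(unique(m$cellId)),
    paste(unique(m$channel), collapse = ", ")))
})

setMethod("show", "ActivationCalibration", function(object) {
  cat(sprintf(
    "ActivationCalibration on '%s': parameters %s, %d bootstrap replicates, tau = %g min\n",
    object@channel, paste(object@parameters, collapse = ", "),
    length(object@bootCurves), object@tau))
})
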