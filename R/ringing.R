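## Ringing-mode feature extraction from single-pixel force cycles.
##
## The adhesion force (point D) is the retract minimum; the restored
## adhesion (point E) is the force at the instant of complete detachment,
## recovered by back-extrapolating a damped-free-oscillator fit of the
## post-detachment ringing; the viscoelastic adhesion is their difference.

## package-level counter for the viscoelastic clamp rule
.afmringCounters <- new.env(parent = emptyenv())
.afmringCounters$viscoelasticClamped <- 0L

#' Number of viscoelastic-adhesion values clamped to zero so far
#'
#' Under noise the fitted restored adhesion can slightly exceed the
#' adhesion minimum; the difference is then clamped to zero and this
#' counter incremented.
#'
#' @param reset reset the counter to zero after reading it
#' @return Integer count.
#' @export
clampCount <- function(reset = FALSE) {
  n <- .afmringCounters$viscoelasticClamped
  if (reset) .afmringCounters$viscoelasticClamped <- 0L
  n
}

#' Segment one force cycle into its phases
#'
#' Labels the cycle phases: baseline before contact (A), contact loading
#' to the maximum load (B-C), retract through the adhesion well (C-D) and
#' the post-detachment ringing (F).  Contact is declared where the force
#' exceeds the baseline by five baseline standard deviations; the
#' detachment instant is the largest positive force step following the
#' global retract minimum (threshold five times the local noise sd).
#'
#' @param trace a [ForceTrace]
#' @return A list with elements `segments` (named list of index ranges),
#'   `detachmentTime`, `detachmentIndex`, `baselineMean`, `noiseSd` and
#'   `noContact` (logical flag; when TRUE the other elements are NA).
#' @export
segmentCycle <- function(trace) {
  stopifnot(is(trace, "ForceTrace"))
  f <- traceForce(trace)
  tt <- traceTime(trace)
  n <- length(f)
  nBase <- max(16L, n %/% 50)
  mu0 <- mean(f[seq_len(nBase)])
  sd0 <- stats::sd(f[seq_len(nBase)])
  span <- diff(range(f))
  thr <- max(5 * sd0, 1e-9 * max(span, 1e-12), 1e-12)
  contactIdx <- which(f > mu0 + thr)[1]
  if (is.na(contactIdx) || span <= thr)
    return(list(segments = NULL, detachmentTime = NA_real_,
                detachmentIndex = NA_integer_, baselineMean = mu0,
                noiseSd = sd0, noContact = TRUE))
  iMax <- which.max(f)
  iMin <- iMax + which.min(f[iMax:n]) - 1L
  steps <- diff(f)
  ## step-noise level from the pre-contact baseline only (the ringing
  ## oscillation would inflate a global estimate)
  noise <- stats::mad(steps[seq_len(max(2L, nBase - 1L))]) / sqrt(2)
  stepThr <- max(5 * noise, 1e-9 * span)
  if (f[iMin] < mu0 - thr) {
    ## the detachment discontinuity terminates the adhesion well, so it
    ## must lie within a fraction of a ringing period of the retract
    ## minimum; restricting the search keeps noisy ring upswings from
    ## masquerading as the detachment step
    win <- iMin:min(n - 1L, iMin + 16L)
    bigStep <- win[steps[win] > stepThr]
    detachIdx <- if (length(bigStep) > 0)
      bigStep[which.max(steps[bigStep])] else iMin
    ringSeg <- if (detachIdx < n) c(detachIdx + 1L, n) else integer(0)
    detachT <- if (detachIdx < n) tt[detachIdx + 1L] else tt[n]
  }
  if (!exists("ringSeg", inherits = FALSE)) {
    ## zero-adhesion cycle: D coincides with the baseline crossing after
    ## the maximum and there is no snap-off, hence no ringing segment
    back <- which(f[iMax:n] <= mu0 + thr)[1]
    detachIdx <- if (is.na(back)) n else iMax + back - 1L
    ringSeg <- integer(0)
    detachT <- tt[detachIdx]
  }
  list(segments = list(
         baseline = c(1L, max(1L, contactIdx - 1L)),
         loading = c(contactIdx, iMax),
         retract = c(iMax, detachIdx),
         ringing = ringSeg),
       detachmentTime = detachT,
       detachmentIndex = detachIdx,
       baselineMean = mu0, noiseSd = sd0, noContact = FALSE)
}

#' Single-point adhesion estimate (HybriD-style retract minimum)
#'
#' The magnitude of the single-sample minimum of the retract segment
#' relative to the baseline.  This is the deliberately noise-sensitive
#' one-data-point estimate that conventional sub-resonance imaging
#' records; it is kept for comparison with the multi-point Ringing-mode
#' estimate.
#'
#' @param trace a [ForceTrace]
#' @param segmentation optional result of [segmentCycle()] (recomputed
#'   when missing)
#' @return Adhesion force magnitude, nN (NA with a no-contact cycle).
#' @export
adhesionMinimum <- function(trace, segmentation = NULL) {
  if (is.null(segmentation)) segmentation <- segmentCycle(trace)
  if (segmentation$noContact) return(NA_real_)
  f <- traceForce(trace)
  seg <- segmentation$segments$retract
  max(0, segmentation$baselineMean - min(f[seg[1]:seg[2]]))
}

#' Restored adhesion by damped-oscillator back-extrapolation
#'
#' Fits `A * exp(-(t - td)/tau) * cos(2 pi f (t - td) + phi) + c` to the
#' post-detachment ringing segment by trust-region least squares
#' (initialised from the configured resonance frequency and the
#' log-envelope slope) and back-extrapolates to the detachment instant:
#' the restored adhesion is the magnitude of the fitted oscillation
#' evaluated at `td`.  The fit is flagged unreliable when the segment
#' holds fewer than three full periods or the residual exceeds 20% of the
#' fitted amplitude.
#'
#' @param trace a [ForceTrace]
#' @param config the [RingingConfig] used for initialisation
#' @param segmentation optional result of [segmentCycle()]
#' @return A list with `restoredAdhesion` (nN), `fitResidual` (rms, nN),
#'   `frequency`, `decayTime`, `unreliable` flag and `reason`.
#' @export
restoredAdhesionFit <- function(trace, config, segmentation = NULL) {
  stopifnot(is(config, "RingingConfig"))
  if (is.null(segmentation)) segmentation <- segmentCycle(trace)
  bad <- function(reason)
    list(restoredAdhesion = NA_real_, fitResidual = NA_real_,
         frequency = NA_real_, decayTime = NA_real_, unreliable = TRUE,
         reason = reason)
  if (segmentation$noContact) return(bad("no contact"))
  seg <- segmentation$segments$ringing
  if (length(seg) == 0) return(bad("empty ringing segment"))
  f0 <- config@resonanceFreq
  tt <- traceTime(trace)
  ff <- traceForce(trace)
  idx <- seg[1]:seg[2]
  td <- segmentation$detachmentTime
  nPeriods <- (tt[idx[length(idx)]] - td) * f0
  if (nPeriods < 3) return(bad("fewer than 3 ringing periods"))
  ## drop the first period from the fit: the detected detachment sample
  ## can sit a few samples early under noise, and pre-detachment well
  ## samples would contaminate the oscillator fit; the back-extrapolation
  ## recovers the envelope at the detachment instant regardless
  if (nPeriods >= 4) idx <- idx[tt[idx] - td > 1 / f0]
  dtau <- tt[idx] - td
  y <- ff[idx]
  tauInit <- config@qualityFactor / (pi * f0)
  ## refine the decay-time initialisation from the log envelope
  pk <- which(diff(sign(diff(abs(y)))) < 0) + 1L
  if (length(pk) >= 3) {
    env <- abs(y[pk])
    keep <- env > 0.02 * max(env)
    if (sum(keep) >= 3) {
      ef <- stats::lm.fit(cbind(1, dtau[pk[keep]]), log(env[keep]))
      sl <- unname(ef$coefficients[2])
      if (is.finite(sl) && sl < 0) tauInit <- -1 / sl
    }
  }
  ## linear initialisation of the in-phase/quadrature amplitudes
  ew <- exp(-dtau / tauInit)
  X <- cbind(ew * cos(2 * pi * f0 * dtau), ew * sin(2 * pi * f0 * dtau), 1)
  init <- stats::lm.fit(X, y)$coefficients
  df <- data.frame(dtau = dtau, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ exp(-dtau / tau) * (p * cos(2 * pi * fr * dtau) +
                              q * sin(2 * pi * fr * dtau)) + c0,
    data = df,
    start = list(p = unname(init[1]), q = unname(init[2]),
                 c0 = unname(init[3]), tau = tauInit, fr = f0),
    lower = c(-Inf, -Inf, -Inf, 1e-9, f0 / 3),
    upper = c(Inf, Inf, Inf, Inf, f0 * 3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(bad("oscillator fit failed"))
  cf <- stats::coef(fit)
  amp <- sqrt(cf[["p"]]^2 + cf[["q"]]^2)
  residRms <- sqrt(mean(stats::resid(fit)^2))
  ## back-extrapolate to the detachment instant: at complete detachment
  ## the cantilever sits at its (negative) oscillation extremum, so the
  ## restored force is the fitted envelope at the nearest negative
  ## extremum phase -- this makes the estimate robust to small errors in
  ## the detected detachment sample
  omega <- 2 * pi * cf[["fr"]]
  psi <- atan2(cf[["q"]], cf[["p"]])
  kcyc <- round(-(psi + pi) / (2 * pi))
  dstar <- (psi + pi + 2 * pi * kcyc) / omega
  restored <- amp * exp(-dstar / cf[["tau"]])
  unreliable <- residRms > 0.2 * amp
  list(restoredAdhesion = as.numeric(restored),
       fitResidual = as.numeric(residRms),
       frequency = as.numeric(cf[["fr"]]),
       decayTime = as.numeric(cf[["tau"]]),
       unreliable = as.logical(unreliable),
       reason = if (isTRUE(unreliable))
         "residual exceeds 20% of amplitude" else NA_character_)
}

#' Viscoelastic adhesion from adhesion and restored adhesion
#'
#' The identity `Fvisc = Fadh - Frest` (the energy-loss signature of
#' inelastic deformation during detachment).  Under noise the fitted
#' restored adhesion can slightly exceed the adhesion force; negative
#' differences are clamped to zero with a warning counter (see
#' [clampCount()]).
#'
#' @param adhesion adhesion force, nN
#' @param restoredAdhesion restored adhesion force, nN
#' @return Viscoelastic adhesion, nN.
#' @export
viscoelasticAdhesion <- function(adhesion, restoredAdhesion) {
  v <- adhesion - restoredAdhesion
  if (is.na(v)) return(NA_real_)
  if (v < 0) {
    .afmringCounters$viscoelasticClamped <-
      .afmringCounters$viscoelasticClamped + 1L
    v <- 0
  }
  v
}

#' Extract all per-pixel curve features from one force cycle
#'
#' @param trace a [ForceTrace]
#' @param config a [RingingConfig]
#' @return A list with adhesion, restoredAdhesion, viscoelasticAdhesion,
#'   maxLoad, deformation, height, detachmentTime, fitResidual and the QC
#'   flags `noContact` / `unreliable`.
#' @export
extractCurveFeatures <- function(trace, config) {
  seg <- segmentCycle(trace)
  truth <- groundTruth(trace)
  if (seg$noContact)
    return(list(adhesion = NA_real_, restoredAdhesion = NA_real_,
                viscoelasticAdhesion = NA_real_, maxLoad = NA_real_,
                deformation = NA_real_, height = NA_real_,
                detachmentTime = NA_real_, fitResidual = NA_real_,
                noContact = TRUE, unreliable = FALSE))
  adh <- adhesionMinimum(trace, seg)
  ringFit <- restoredAdhesionFit(trace, config, seg)
  rest <- ringFit$restoredAdhesion
  visc <- if (is.na(rest)) NA_real_ else viscoelasticAdhesion(adh, rest)
  list(adhesion = adh,
       restoredAdhesion = rest,
       viscoelasticAdhesion = visc,
       maxLoad = max(traceForce(trace)) - seg$baselineMean,
       ## deformation and height are pass-through channels: they require
       ## the z-trajectory, which synthetic traces carry as ground truth
       deformation = truth$deformation %||% NA_real_,
       height = truth$height %||% NA_real_,
       detachmentTime = seg$detachmentTime,
       fitResidual = ringFit$fitResidual,
       noContact = FALSE,
       unreliable = isTRUE(ringFit$unreliable))
}

## 4-neighbour median infill of flagged pixels.
.medianInfill <- function(v, mask) {
  m <- nrow(v); n <- ncol(v)
  out <- v
  for (idx in which(mask)) {
    i <- (idx - 1L) %% m + 1L
    j <- (idx - 1L) %/% m + 1L
    nb <- c(if (i > 1) v[i - 1, j], if (i < m) v[i + 1, j],
            if (j > 1) v[i, j - 1], if (j < n) v[i, j + 1])
    nb <- nb[!is.na(nb)]
    out[i, j] <- if (length(nb) > 0) stats::median(nb) else 0
  }
  out
}

#' Assemble channel maps from a grid of force cycles
#'
#' Extracts curve features for every pixel of a complete square grid of
#' traces and assembles one [SurfaceMap] per channel (height, adhesion,
#' restored adhesion, viscoelastic adhesion, max load, deformation).
#' Pixels flagged no-contact or unreliable are recorded in the QC mask and
#' filled by the median of their 4-neighbours.
#'
#' @param traces a list-matrix of [ForceTrace] objects (as from
#'   [simulateForceGrid()])
#' @param config a [RingingConfig]
#' @param pixelPitch pixel pitch of the resulting maps, nm
#' @return A list with `maps` (named list of [SurfaceMap]) and `qcMask`
#'   (logical matrix, TRUE = flagged).
#' @export
processGrid <- function(traces, config, pixelPitch = 20) {
  if (!is.list(traces) || is.null(dim(traces)))
    stop("'traces' must be a list-matrix with a dim attribute")
  m <- nrow(traces); n <- ncol(traces)
  if (m != n || m %% 2L != 0L)
    stop("the trace grid must be square with an even side")
  channels <- c("height", "adhesion", "restored adhesion",
                "viscoelastic adhesion", "max load", "deformation")
  fields <- c("height", "adhesion", "restoredAdhesion",
              "viscoelasticAdhesion", "maxLoad", "deformation")
  vals <- lapply(fields, function(f) matrix(NA_real_, m, n))
  names(vals) <- fields
  qc <- matrix(FALSE, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    ft <- extractCurveFeatures(traces[[i, j]], config)
    qc[i, j] <- ft$noContact || ft$unreliable
    for (f in fields) vals[[f]][i, j] <- ft[[f]]
  }
  maps <- list()
  for (k in seq_along(fields)) {
    v <- vals[[fields[k]]]
    v[qc] <- NA_real_
    if (all(is.na(v))) {
      v[] <- 0
    } else {
      v[is.na(v)] <- NA_real_
      v <- .medianInfill(v, is.na(v))
    }
    un <- if (channels[k] %in% c("height", "deformation")) "nm" else "nN"
    maps[[channels[k]]] <- surfaceMap(v, pixelPitch = pixelPitch,
                                      channel = channels[k], units = un,
                                      provenance = "processGrid")
  }
  list(maps = maps, qcMask = qc)
}
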