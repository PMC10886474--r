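## Synthetic neutrophil-like cell-surface maps.
##
## The generative model is a two-component mixture controlled by a latent
## activation level a in [0, 1]:
##
##   field = (1 - a) * fold + a * grain  (+ white pixel noise),
##
## where `fold` is an oriented long-wavelength Gaussian random field (the
## folded membrane of a resting cell: a narrow spectral annulus at the fold
## wavelength with a preferred wave-vector direction) and `grain` is an
## isotropic granular field (Gaussian blobs of radius grainRadius at a
## density that grows with activation, mixed with a Gaussian random field of
## identical spectrum so that the height distribution stays near-Gaussian at
## every level).  After construction the field is rescaled to an exact
## target RMS, so amplitude parameters are held constant across activation
## levels and only the spatial organisation changes; a plane tilt is added
## last.  Grain amplitudes are symmetric (bumps and pits) for the same
## reason.

## fold : grain intrinsic RMS ratio at equal mixture weight.  Folds are a
## subtle large-scale modulation of the effective height: their power is
## deliberately small next to the granular relief, while their spectral
## concentration keeps them visible to amplitude-spectrum statistics.
.FOLD_AMPLITUDE <- 0.44

## structure-factor suppression width (units of grain radius) and depth
.EXCLUSION_FACTOR <- 2.5
.EXCLUSION_STRENGTH <- 0.9

## power share of the oriented ring within the fold field (the rest is the
## isotropic skirt annulus)
.FOLD_RING_SHARE <- 0.36

## Membrane-fold random field, unit RMS: a narrow oriented spectral ring
## at the fold wavelength (the quasi-periodic, direction-selective part of
## the fold pattern) plus an isotropic annular skirt at the same
## wavelength (fold segments of all orientations), both Gaussian fields.
.foldField <- function(m, pitchNm, wavelengthNm, anisotropy, direction,
                       ringShare = .FOLD_RING_SHARE) {
  ext <- m * pitchNm
  rf <- ext / wavelengthNm              # annulus radius in index units
  k <- .centredIndex(m)
  kx <- matrix(rep(k, each = m), m)
  ky <- matrix(rep(k, times = m), m)
  r <- sqrt(kx^2 + ky^2)
  ring <- exp(-(r - rf)^2 / (2 * max(rf / 3, 2.5)^2))
  if (anisotropy > 0.01) {
    theta <- atan2(ky, kx)
    dth <- abs(((theta - direction) + pi / 2) %% pi - pi / 2)
    sigTh <- (1 - anisotropy) * 0.4 + 0.04
    ring <- ring * exp(-dth^2 / (2 * sigTh^2))
  }
  skirt <- exp(-(r - rf)^2 / (2 * max(rf / 4, 2)^2))
  ring[1, 1] <- 0; skirt[1, 1] <- 0      # no DC
  ring <- ring / sqrt(sum(ring^2))
  skirt <- skirt / sqrt(sum(skirt^2))
  filt <- sqrt(ringShare * ring^2 + (1 - ringShare) * skirt^2)
  f <- stats::fft(matrix(stats::rnorm(m * m), m)) * filt
  z <- Re(stats::fft(f, inverse = TRUE)) / length(f)
  z / rmsAboutMean(z)
}

## Granular field: symmetric Gaussian blobs at Poisson-like density, mixed
## with a Gaussian random field of the same spectrum.  The blob kernel
## carries a structure-factor-like low-frequency suppression (granules are
## solid bodies with a minimum spacing, so long-wavelength clustering is
## suppressed), which makes the granular band broadband rather than peaked
## at the image scale.  `bumpShare` is the variance share of the discrete
## blobs.
.grainField <- function(m, pitchNm, sigmaNm, nGrains, bumpShare = 0.4,
                        exclusionFactor = 2.5, exclusionStrength = 0.95) {
  sigPx <- sigmaNm / pitchNm
  k <- .centredIndex(m)
  kx <- matrix(rep(k, each = m), m)
  ky <- matrix(rep(k, times = m), m)
  f2 <- (kx / m)^2 + (ky / m)^2
  kern <- exp(-2 * pi^2 * sigPx^2 * f2) *
    (1 - exclusionStrength *
       exp(-2 * pi^2 * (exclusionFactor * sigPx)^2 * f2))
  kern[1, 1] <- 0                        # keep fields zero-mean
  impulses <- numeric(m * m)
  pos <- sample.int(m * m, nGrains, replace = TRUE)
  amp <- stats::rnorm(nGrains)
  tab <- rowsum(amp, pos)
  impulses[as.integer(rownames(tab))] <- tab[, 1]
  bumps <- Re(stats::fft(stats::fft(matrix(impulses, m)) * kern,
                         inverse = TRUE)) / (m * m)
  gauss <- Re(stats::fft(stats::fft(matrix(stats::rnorm(m * m), m)) * kern,
                         inverse = TRUE)) / (m * m)
  bumps <- bumps / rmsAboutMean(bumps)
  gauss <- gauss / rmsAboutMean(gauss)
  z <- sqrt(bumpShare) * bumps + sqrt(1 - bumpShare) * gauss
  z / rmsAboutMean(z)
}

#' Generate a synthetic cell-surface map
#'
#' Builds one surface realisation from the fold + grain mixture model (see
#' [surfaceConfig()]): an oriented membrane-fold field with weight
#' `1 - activationLevel`, an isotropic granular field with weight
#' `activationLevel` whose grain count scales as
#' `grainDensity * (0.2 + 0.8 * activationLevel)` per um^2, plus white
#' pixel noise.  The field is rescaled to `targetRms` exactly (before the
#' plane tilt is added), so the RMS amplitude carries no activation
#' information by construction.
#'
#' @param config a [SurfaceConfig]
#' @param seed integer seed; all randomness in the map flows from it
#' @param channel,units labels attached to the returned map
#' @return A [SurfaceMap]; `groundTruth(map)` carries the realised grain
#'   count and the configuration.
#' @examples
#' m0 <- generateSurface(surfaceConfig(activationLevel = 0), seed = 1)
#' m1 <- generateSurface(surfaceConfig(activationLevel = 1), seed = 1)
#' @export
generateSurface <- function(config, seed, channel = "restored adhesion",
                            units = "nN") {
  stopifnot(is(config, "SurfaceConfig"))
  validObject(config)
  m <- config@gridSize
  a <- config@activationLevel
  withSeed(seed, {
    field <- matrix(0, m, m)
    if (a < 1) {
      ## the fold modulation is intrinsically weaker than the granular
      ## relief (folds are a subtle large-scale modulation of the
      ## effective height); .FOLD_AMPLITUDE sets the fold:grain RMS ratio
      ## at equal mixture weight
      field <- field + (1 - a) * .FOLD_AMPLITUDE *
        .foldField(m, config@pixelPitch, config@foldWavelength,
                   config@foldAnisotropy, config@foldDirection)
    }
    nGrains <- 0L
    if (a > 0) {
      areaUm2 <- (m * config@pixelPitch * 1e-3)^2
      lambda <- config@grainDensity * (0.2 + 0.8 * a) * areaUm2
      nGrains <- max(1L, stats::rpois(1, lambda))
      field <- field + a *
        .grainField(m, config@pixelPitch, config@grainRadius, nGrains,
                    exclusionFactor = .EXCLUSION_FACTOR,
                    exclusionStrength = .EXCLUSION_STRENGTH)
    }
    field <- field - mean(field)
    s <- rmsAboutMean(field)
    if (s > 0) field <- field / s
    if (config@noiseSd > 0)
      field <- field + matrix(stats::rnorm(m * m, sd = config@noiseSd), m)
    field <- field - mean(field)
    field <- field * (config@targetRms / rmsAboutMean(field))
    if (any(config@planeTilt != 0)) {
      coord <- (seq_len(m) - 1) * config@pixelPitch
      field <- field +
        outer(rep(1, m), coord) * config@planeTilt[1] +   # x along columns
        outer(coord, rep(1, m)) * config@planeTilt[2]     # y along rows
    }
    surfaceMap(field, pixelPitch = config@pixelPitch, channel = channel,
               units = units,
               provenance = sprintf("synthetic fold+grain seed %d", seed),
               metadata = list(truth = list(
                 activationLevel = a, nGrains = nGrains, config = config,
                 seed = seed)))
  })
}

#' Saturating activation level as a function of exposure time
#'
#' `level(t) = 1 - exp(-t / tau)`: the latent activation level approached
#' exponentially with saturation constant `tau` (minutes), so that with the
#' default `tau = 10` the level reaches 95% of its plateau by 30 minutes.
#'
#' @param timeMin exposure time(s), minutes
#' @param tau saturation constant, minutes
#' @return Activation level(s) in \[0, 1).
#' @examples
#' activationLevel(c(0, 5, 10, 30, 60, 120))
#' @export
activationLevel <- function(timeMin, tau = 10) 1 - exp(-timeMin / tau)

#' Invert the saturating level curve to an exposure time
#'
#' @param level activation level(s) in \[0, 1)
#' @param tau saturation constant, minutes
#' @return Exposure time(s), minutes.
#' @export
levelToMinutes <- function(level, tau = 10) {
  level <- clamp(level, 0, 1 - 1e-9)
  -tau * log(1 - level)
}

## Per-cell parameter spread. The study reports no cell-to-cell variability
## magnitudes, so these spreads are invented defaults (documented): modest
## log-normal jitter on scales and amplitudes, a uniform random fold
## direction, and a clamped Gaussian jitter on anisotropy and level.
.cellJitter <- function(base, cellSeed, level, heightChannel = FALSE) {
  withSeed(cellSeed, {
    cfg <- base
    cfg@foldWavelength <- base@foldWavelength * exp(stats::rnorm(1, 0, 0.05))
    cfg@grainRadius <- max(base@pixelPitch,
                           base@grainRadius * exp(stats::rnorm(1, 0, 0.02)))
    cfg@foldAnisotropy <- clamp(
      base@foldAnisotropy + stats::rnorm(1, 0, 0.10), 0.05, 0.95)
    cfg@foldDirection <- stats::runif(1, 0, pi)
    cfg@targetRms <- base@targetRms * exp(stats::rnorm(1, 0, 0.10))
    cfg@noiseSd <- base@noiseSd * exp(stats::rnorm(1, 0, 0.05))
    lvl <- if (level > 0)
      clamp(level + stats::rnorm(1, 0, 0.02), 0, 1) else 0
    cfg@activationLevel <- lvl
    cfg
  })
}

#' Generate a synthetic activation time-course
#'
#' Emulates the study design: two control groups at activation level 0
#' (`CTR 0m`, `CTR 120m`) and one activated group per exposure time, with
#' `nCells` cells each.  The latent level follows
#' `activationLevel(t, tau)`, saturating within about 30 minutes for the
#' default `tau = 10` min.  Per cell, three channel maps are generated:
#' `height` (structure held time-invariant, with a random plane tilt),
#' `restored adhesion` (full activation dependence) and
#' `viscoelastic adhesion` (activation dependence with more noise).
#' Cell-to-cell variability is applied to the configuration with a
#' documented (invented) spread; each map's randomness derives
#' deterministically from `seed`.
#'
#' @param times activation times, minutes (non-empty)
#' @param nCells cells per group (>= 3)
#' @param base a [SurfaceConfig] used for the restored-adhesion channel
#' @param tau saturation constant, minutes
#' @param seed integer seed
#' @param channels subset of the three channel names to generate
#' @return An [ActivationSeries].
#' @examples
#' ser <- generateActivationSeries(times = c(5, 30), nCells = 3,
#'                                 base = surfaceConfig(gridSize = 64),
#'                                 seed = 1)
#' seriesManifest(ser)[1:4, ]
#' @export
generateActivationSeries <- function(times = c(5, 10, 30, 60, 120),
                                     nCells = 20,
                                     base = surfaceConfig(targetRms = 0.35),
                                     tau = 10, seed = 1,
                                     channels = c("height",
                                                  "restored adhesion",
                                                  "viscoelastic adhesion")) {
  if (length(times) == 0) stop("'times' must be non-empty")
  if (nCells < 3) stop("'nCells' must be >= 3")
  channels <- match.arg(channels, several.ok = TRUE,
                        choices = c("height", "restored adhesion",
                                    "viscoelastic adhesion"))
  groups <- data.frame(
    group = c("CTR 0m", "CTR 120m", sprintf("ACT %gm", times)),
    timeMin = c(0, 120, times),
    level = c(0, 0, activationLevel(times, tau)),
    stringsAsFactors = FALSE)
  rows <- list()
  maps <- list()
  for (g in seq_len(nrow(groups))) {
    for (cell in seq_len(nCells)) {
      cellSeed <- deriveSeed(seed, g, cell)
      cellCfg <- .cellJitter(base, cellSeed, groups$level[g])
      for (ch in channels) {
        chIdx <- match(ch, c("height", "restored adhesion",
                             "viscoelastic adhesion"))
        cfg <- cellCfg
        if (ch == "height") {
          ## height structure carries no activation signal; tilt present
          cfg@activationLevel <- 0
          cfg@targetRms <- 40 * cfg@targetRms / base@targetRms
          tiltSeed <- deriveSeed(cellSeed, 17L)
          cfg@planeTilt <- withSeed(tiltSeed, stats::rnorm(2, 0, 0.004))
          un <- "nm"
        } else if (ch == "viscoelastic adhesion") {
          cfg@targetRms <- 0.7 * cfg@targetRms
          cfg@noiseSd <- 1.5 * cfg@noiseSd
          un <- "nN"
        } else un <- "nN"
        mapSeed <- deriveSeed(cellSeed, 100L + chIdx)
        mp <- generateSurface(cfg, seed = mapSeed, channel = ch,
                              units = un)
        id <- sprintf("%s_cell%02d_%s", gsub(" ", "", groups$group[g]),
                      cell, gsub(" ", "_", ch))
        maps[[id]] <- mp
        rows[[length(rows) + 1L]] <- data.frame(
          mapId = id, group = groups$group[g],
          timeMin = groups$timeMin[g], cellId = cell, channel = ch,
          activationLevel = cfg@activationLevel,
          stringsAsFactors = FALSE)
      }
    }
  }
  new("ActivationSeries", manifest = do.call(rbind, rows), maps = maps)
}
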