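## Shared fixtures, computed lazily and cached for the whole run.

.testCache <- new.env(parent = emptyenv())

## The default synthetic activation study: 2 control + 5 activated groups,
## 20 cells each, three channels.  Used by the activation and acceptance
## tests; computed once (~2-3 min).
cachedSeries <- function() {
  if (is.null(.testCache$series))
    .testCache$series <- generateActivationSeries(seed = 1)
  .testCache$series
}

cachedSeriesSE <- function() {
  if (is.null(.testCache$se))
    .testCache$se <- seriesParameters(cachedSeries())
  .testCache$se
}

## Small toy SummarizedExperiment with hand-set parameter values, for the
## statistics that don't need real maps.
toySE <- function(values, groups, times, channel = "restored adhesion") {
  nm <- parameterNames()
  mat <- matrix(rep(values, each = length(nm)), nrow = length(nm),
                dimnames = list(nm, NULL))
  man <- data.frame(
    mapId = sprintf("m%02d", seq_along(values)), group = groups,
    timeMin = times, cellId = seq_along(values), channel = channel,
    activationLevel = ifelse(grepl("^CTR", groups), 0,
                             activationLevel(times)))
  colnames(mat) <- man$mapId
  SummarizedExperiment::SummarizedExperiment(
    assays = list(parameters = mat),
    colData = S4Vectors::DataFrame(man, row.names = man$mapId))
}

## Independent brute-force oracles for the spectrum reductions: plain
## double loops over half-plane pixels, nearest-line / rounded-radius
## binning.
bruteAngular <- function(amp, nLines) {
  m <- nrow(amp)
  centre <- m %/% 2 + 1L
  a <- numeric(nLines)
  for (row in seq_len(m)) for (col in seq_len(m)) {
    kx <- col - centre
    ky <- row - centre
    if (!(ky > 0 || (ky == 0 && kx > 0))) next
    theta <- atan2(ky, kx)
    i <- round(theta / (pi / nLines)) %% nLines
    a[i + 1] <- a[i + 1] + amp[row, col]
  }
  a
}

bruteRadial <- function(amp) {
  m <- nrow(amp)
  centre <- m %/% 2 + 1L
  rmax <- m %/% 2 - 1L
  b <- numeric(rmax)
  for (row in seq_len(m)) for (col in seq_len(m)) {
    kx <- col - centre
    ky <- row - centre
    if (!(ky > 0 || (ky == 0 && kx > 0))) next
    r <- round(sqrt(kx^2 + ky^2))
    if (r >= 1 && r <= rmax) b[r] <- b[r] + amp[row, col]
  }
  b
}

## A cosine surface along image x with an integer number of wavelengths.
cosineMap <- function(m = 256, cycles = 8, pitch = 20, amplitude = 1) {
  x <- matrix(rep(0:(m - 1), each = m), m)
  surfaceMap(amplitude * cos(2 * pi * cycles * x / m), pixelPitch = pitch,
             channel = "height", units = "nm")
}
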