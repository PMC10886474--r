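## The 37-parameter areal surface texture suite.
##
## Definitions follow ISO 25178-2 / ISO 4287 practice as implemented in
## surface-metrology software; where a definition admits variants the
## convention used here is stated in the registry below.  Undefined values
## (e.g. skewness of a constant map) are reported as NA.

.PARAM_FAMILIES <- list(
  amplitude = c("Smean", "Sa", "Sq", "Ssk", "Sku", "Sp", "Sv", "Sz",
                "S10z"),
  spatial = c("Sal", "Str20", "Str37", "Std", "Stdi", "Srw", "Srwi",
              "Shw", "Sfd"),
  hybrid = c("Sdq", "Sdq6", "Sdr", "Ssc", "Sds", "S2A", "S3A"),
  functional = c("Sbi", "Sci", "Svi", "Sk", "Spk", "Svk", "Smr1", "Smr2",
                 "Sdc0-5", "Sdc5-10", "Sdc10-50", "Sdc50-95")
)

#' Names (and families) of the 37 surface parameters
#'
#' @param byFamily return a list split by parameter family
#' @return Character vector of the 37 parameter names, or a named list.
#' @examples
#' length(parameterNames())
#' @export
parameterNames <- function(byFamily = FALSE) {
  if (byFamily) .PARAM_FAMILIES else unlist(.PARAM_FAMILIES,
                                            use.names = FALSE)
}

## Strict 8-neighbour local maxima of interior pixels.
.localMaxima <- function(z) {
  m <- nrow(z); n <- ncol(z)
  core <- z[2:(m - 1), 2:(n - 1)]
  res <- core > z[1:(m - 2), 2:(n - 1)] & core > z[3:m, 2:(n - 1)] &
    core > z[2:(m - 1), 1:(n - 2)] & core > z[2:(m - 1), 3:n] &
    core > z[1:(m - 2), 1:(n - 2)] & core > z[1:(m - 2), 3:n] &
    core > z[3:m, 1:(n - 2)] & core > z[3:m, 3:n]
  which(res, arr.ind = TRUE) + 1L       # indices in the full matrix
}

## Circular normalised autocorrelation via the Wiener-Khinchin relation.
.circularAcf <- function(d) {
  f <- stats::fft(d)
  acf <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / length(d)
  acf <- fftShift2(acf)
  acf / acf[nrow(d) %/% 2 + 1L, nrow(d) %/% 2 + 1L]
}

## Distance (pixels) at which the ACF first decays below `s` along each of
## `nAngles` directions; censored at rmax when it never crosses.
.acfDecayLengths <- function(acf, s, nAngles = 180L) {
  m <- nrow(acf)
  centre <- m %/% 2 + 1L
  rmax <- m %/% 2 - 1L
  ang <- (seq_len(nAngles) - 1L) * pi / nAngles
  radii <- seq_len(rmax)
  px <- outer(radii, cos(ang))
  py <- outer(radii, sin(ang))
  vals <- .bilinear(acf, centre + py, centre + px)
  out <- numeric(nAngles)
  for (j in seq_len(nAngles)) {
    v <- c(1, vals[, j])                 # r = 0 has ACF 1
    below <- which(v < s)
    if (length(below) == 0 || all(is.na(v[-1]))) { out[j] <- rmax; next }
    i <- below[1]                        # first sample below threshold
    r1 <- i - 1; r0 <- i - 2
    v1 <- v[i]; v0 <- v[i - 1]
    out[j] <- r0 + (v0 - s) / (v0 - v1) * (r1 - r0)
  }
  out
}

## Abbott-Firestone (bearing) curve: height at material ratio p, linear
## interpolation through the sorted heights.
.bearingHeight <- function(sortedDesc, p) {
  n <- length(sortedDesc)
  probs <- (seq_len(n) - 0.5) / n
  stats::approx(probs, sortedDesc, xout = p, rule = 2)$y
}

## Void volume per unit area below the bearing level p:
##   Vv(p) = integral_p^1 (h(p) - h(q)) dq.
.voidVolume <- function(sortedDesc, p) {
  n <- length(sortedDesc)
  probs <- (seq_len(n) - 0.5) / n
  hp <- .bearingHeight(sortedDesc, p)
  q <- probs[probs >= p]
  h <- sortedDesc[probs >= p]
  if (length(q) < 2) return(0)
  grid <- c(p, q, 1)
  vals <- c(hp - hp, hp - h, hp - h[length(h)])
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

## Sk family from the bearing curve: minimal-slope 40% secant window.
.coreParameters <- function(sortedDesc) {
  n <- length(sortedDesc)
  p <- (seq_len(n) - 0.5) / n
  grid <- seq(0, 0.6, by = 0.005)
  h0 <- .bearingHeight(sortedDesc, grid)
  h1 <- .bearingHeight(sortedDesc, grid + 0.4)
  drop <- h0 - h1
  i <- which.min(drop)
  slope <- (h1[i] - h0[i]) / 0.4
  intercept <- h0[i] - slope * grid[i]
  zTop <- intercept                      # line value at p = 0
  zBot <- intercept + slope              # line value at p = 1
  sk <- zTop - zBot
  smr1 <- if (sortedDesc[1] <= zTop) 0 else
    stats::approx(rev(sortedDesc), rev(p), xout = zTop, rule = 2,
                  ties = "ordered")$y
  smr2 <- if (sortedDesc[n] >= zBot) 1 else
    stats::approx(rev(sortedDesc), rev(p), xout = zBot, rule = 2,
                  ties = "ordered")$y
  above <- p <= smr1
  a1 <- if (smr1 > 0 && any(above))
    sum(pmax(sortedDesc[above] - zTop, 0)) / n else 0
  below <- p >= smr2
  a2 <- if (smr2 < 1 && any(below))
    sum(pmax(zBot - sortedDesc[below], 0)) / n else 0
  spk <- if (smr1 > 0) 2 * a1 / smr1 else 0
  svk <- if (smr2 < 1) 2 * a2 / (1 - smr2) else 0
  list(Sk = sk, Spk = spk, Svk = svk, Smr1 = 100 * smr1,
       Smr2 = 100 * smr2)
}

#' Compute the 37-parameter surface texture suite for one map
#'
#' Evaluates the full registry of 37 areal parameters (see
#' [parameterNames()]) on one channel map: nine amplitude parameters, nine
#' spatial parameters (including the 2D-Fourier indices Stdi, Srwi and Shw
#' and autocorrelation-based Sal/Str), seven hybrid parameters and twelve
#' functional (bearing-curve) parameters.  Adhesion-channel maps are
#' treated as "effective height": the adhesion value at each pixel plays
#' the role of a height.  Height maps should be tilt-corrected with
#' [removePlaneTilt()] before calling this function.
#'
#' Parameters that are undefined for the given map (e.g. `Ssk`/`Sku` of a
#' constant map, spatial indices of an all-zero spectrum) are returned as
#' `NA`.
#'
#' @param map a [SurfaceMap]
#' @param nLines number of angular lines for the angular spectrum
#'   (default: image size)
#' @param halfFactor `Shw` convention switch, see [sHw()]
#' @param binning angular binning method, see [amplitudeSpectrum()]
#' @return Named numeric vector with exactly 37 entries.
#' @examples
#' p <- parameterSuite(generateSurface(surfaceConfig(gridSize = 64),
#'                                     seed = 1))
#' p[c("Sq", "Stdi", "Srwi", "Shw")]
#' @export
parameterSuite <- function(map, nLines = NULL, halfFactor = TRUE,
                           binning = c("line", "sector")) {
  stopifnot(is(map, "SurfaceMap"))
  binning <- match.arg(binning)
  z <- map@values
  if (any(!is.finite(z))) stop("map contains non-finite values")
  m <- nrow(z)
  dx <- map@pixelPitch
  out <- stats::setNames(rep(NA_real_, 37), parameterNames())

  mu <- mean(z)
  d <- z - mu
  sq <- sqrt(mean(d^2))
  out["Smean"] <- mu
  out["Sa"] <- mean(abs(d))
  out["Sq"] <- sq
  if (sq > 0) {
    out["Ssk"] <- mean(d^3) / sq^3
    out["Sku"] <- mean(d^4) / sq^4
  }
  out["Sp"] <- max(d)
  out["Sv"] <- -min(d)
  out["Sz"] <- out["Sp"] + out["Sv"]

  peaks <- .localMaxima(d)
  valleys <- .localMaxima(-d)
  if (nrow(peaks) > 0 && nrow(valleys) > 0) {
    ph <- sort(d[peaks], decreasing = TRUE)
    vh <- sort(d[valleys])
    k <- min(5L, length(ph), length(vh))
    out["S10z"] <- (sum(ph[seq_len(k)]) - sum(vh[seq_len(k)])) / k
  }

  ## --- spatial family -----------------------------------------------------
  if (sq > 0) {
    spec <- amplitudeSpectrum(map, nLines = nLines, method = binning)
    a <- spec@angular
    b <- spec@radial
    out["Stdi"] <- sTdi(spec)
    out["Srwi"] <- sRwi(spec)
    out["Shw"] <- sHw(spec, halfFactor = halfFactor)
    if (max(a) > 0)
      out["Std"] <- (which.max(a) - 1) * 180 / length(a)
    if (max(b) > 0) {
      prof <- ifelse(spec@radialCounts > 0,
                     b / pmax(spec@radialCounts, 1), 0)
      out["Srw"] <- dx * (m - 1) / which.max(prof)
    }
    ## fractal dimension from the log-log slope of the mean amplitude per
    ## annulus over the fine-scale regime (self-affine scaling is an
    ## asymptotic fine-scale property); D = 4 + slope, clipped to the
    ## admissible [2, 3]
    cnt <- spec@radialCounts
    rs <- seq_along(b)
    sel <- rs >= m / 8 & b > 0 & cnt > 0
    if (sum(sel) >= 4) {
      mAmp <- b[sel] / cnt[sel]
      fit <- stats::lm.fit(cbind(1, log(rs[sel])), log(mAmp))
      out["Sfd"] <- clamp(4 + fit$coefficients[2], 2, 3)
    }
    acf <- .circularAcf(d)
    len20 <- .acfDecayLengths(acf, 0.2)
    len37 <- .acfDecayLengths(acf, exp(-1))
    out["Sal"] <- dx * min(len20)
    out["Str20"] <- min(len20) / max(len20)
    out["Str37"] <- min(len37) / max(len37)
  }

  ## --- hybrid family ------------------------------------------------------
  ix <- 2:(m - 1)
  gx <- (z[ix, 3:m] - z[ix, 1:(m - 2)]) / (2 * dx)   # x along columns
  gy <- (z[3:m, ix] - z[1:(m - 2), ix]) / (2 * dx)
  out["Sdq"] <- sqrt(mean(gx[, ix - 1]^2) + mean(gy[ix - 1, ]^2))
  if (m >= 8) {
    cf <- c(-1, 9, -45, 0, 45, -9, 1) / (60 * dx)
    ii <- 4:(m - 3)
    g6x <- matrix(0, length(ii), length(ii))
    g6y <- matrix(0, length(ii), length(ii))
    for (o in -3:3) {
      if (cf[o + 4] == 0) next
      g6x <- g6x + cf[o + 4] * z[ii, ii + o]
      g6y <- g6y + cf[o + 4] * z[ii + o, ii]
    }
    out["Sdq6"] <- sqrt(mean(g6x^2) + mean(g6y^2))
  }
  ## developed area by cell triangulation: triangles (a,b,c) and (b,d,c)
  za <- z[1:(m - 1), 1:(m - 1)]; zb <- z[1:(m - 1), 2:m]
  zc <- z[2:m, 1:(m - 1)]; zd <- z[2:m, 2:m]
  area1 <- 0.5 * sqrt(dx^2 * (za - zb)^2 + dx^2 * (za - zc)^2 + dx^4)
  area2 <- 0.5 * sqrt(dx^2 * (zd - zc)^2 + dx^2 * (zd - zb)^2 + dx^4)
  s3 <- sum(area1 + area2)
  s2 <- ((m - 1) * dx)^2
  out["Sdr"] <- 100 * (s3 - s2) / s2
  out["S2A"] <- s2 * 1e-6                 # um^2
  out["S3A"] <- s3 * 1e-6                 # um^2
  areaUm2 <- s2 * 1e-6
  if (nrow(peaks) > 0) {
    pr <- peaks[, 1]; pc <- peaks[, 2]
    zxx <- (z[cbind(pr, pc + 1L)] - 2 * z[peaks] +
              z[cbind(pr, pc - 1L)]) / dx^2
    zyy <- (z[cbind(pr + 1L, pc)] - 2 * z[peaks] +
              z[cbind(pr - 1L, pc)]) / dx^2
    out["Ssc"] <- mean(-(zxx + zyy) / 2)
    out["Sds"] <- nrow(peaks) / areaUm2
  } else {
    out["Sds"] <- 0
  }

  ## --- functional family --------------------------------------------------
  sd_ <- sort(as.numeric(d), decreasing = TRUE)
  h <- function(p) .bearingHeight(sd_, p)
  if (sq > 0) {
    h05 <- h(0.05)
    if (h05 > 0) out["Sbi"] <- sq / h05
    vv05 <- .voidVolume(sd_, 0.05)
    vv80 <- .voidVolume(sd_, 0.8)
    out["Sci"] <- (vv05 - vv80) / sq
    out["Svi"] <- vv80 / sq
    core <- .coreParameters(sd_)
    out["Sk"] <- core$Sk
    out["Spk"] <- core$Spk
    out["Svk"] <- core$Svk
    out["Smr1"] <- core$Smr1
    out["Smr2"] <- core$Smr2
  }
  out["Sdc0-5"] <- h(0) - h(0.05)
  out["Sdc5-10"] <- h(0.05) - h(0.10)
  out["Sdc10-50"] <- h(0.10) - h(0.50)
  out["Sdc50-95"] <- h(0.50) - h(0.95)
  out
}
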