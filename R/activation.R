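## Aggregation, correlation screening and activation-level estimation
## across an activation time-course of parameter sets.

#' Compute the parameter suite for every map of an activation series
#'
#' Runs [parameterSuite()] on each map (height maps are tilt-corrected
#' with [removePlaneTilt()] first; adhesion channels are used as is) and
#' assembles a `SummarizedExperiment`: rows are the 37 parameters, columns
#' are maps, and the column data carries the series manifest (group,
#' activation time, cell id, channel, latent level).
#'
#' @param series an [ActivationSeries]
#' @param tiltRemoveHeight tilt-correct height maps first (default TRUE)
#' @param ... passed on to [parameterSuite()]
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"parameters"`.
#' @export
seriesParameters <- function(series, tiltRemoveHeight = TRUE, ...) {
  stopifnot(is(series, "ActivationSeries"))
  man <- seriesManifest(series)
  maps <- seriesMaps(series)
  mat <- vapply(man$mapId, function(id) {
    mp <- maps[[id]]
    if (tiltRemoveHeight && channelName(mp) == "height")
      mp <- removePlaneTilt(mp)
    parameterSuite(mp, ...)
  }, numeric(37))
  colnames(mat) <- man$mapId
  SummarizedExperiment::SummarizedExperiment(
    assays = list(parameters = mat),
    colData = S4Vectors::DataFrame(man, row.names = man$mapId))
}

.assayLong <- function(se) {
  mat <- SummarizedExperiment::assay(se, "parameters")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  list(mat = mat, cd = cd)
}

#' Summarise a parameter series by group, channel and parameter
#'
#' @param se a `SummarizedExperiment` from [seriesParameters()]
#' @return A data.frame with one row per group x channel x parameter:
#'   mean, sd and n.  Missing parameter values propagate to NA summaries.
#' @export
summarizeSeries <- function(se) {
  x <- .assayLong(se)
  groups <- unique(x$cd$group)
  channels <- unique(x$cd$channel)
  if (any(table(x$cd$group) == 0) || length(groups) == 0)
    stop("empty group in the series")
  out <- list()
  for (g in groups) for (ch in channels) {
    sel <- x$cd$group == g & x$cd$channel == ch
    if (!any(sel)) stop(sprintf("empty group '%s' / channel '%s'", g, ch))
    sub <- x$mat[, sel, drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      group = g, channel = ch, parameter = rownames(sub),
      mean = rowMeans(sub), sd = apply(sub, 1, stats::sd),
      n = ncol(sub), row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Test control-group stability of one parameter
#'
#' Two-sided Mann-Whitney comparison of the parameter between the two
#' control groups (`CTR 0m` vs `CTR 120m`); the parameter is "stable"
#' when p >= 0.05 and the absolute standardised mean difference is below
#' 0.5.  With fewer than three cells per control group the test is
#' flagged unevaluable.
#'
#' @param se a `SummarizedExperiment` from [seriesParameters()]
#' @param parameter parameter name
#' @param channel channel name
#' @return A list with `pValue`, `stdDiff`, `stable` and `evaluable`.
#' @export
controlStability <- function(se, parameter, channel) {
  x <- .assayLong(se)
  v0 <- x$mat[parameter, x$cd$group == "CTR 0m" & x$cd$channel == channel]
  v1 <- x$mat[parameter, x$cd$group == "CTR 120m" &
                x$cd$channel == channel]
  v0 <- v0[!is.na(v0)]; v1 <- v1[!is.na(v1)]
  if (length(v0) < 3 || length(v1) < 3)
    return(list(pValue = NA_real_, stdDiff = NA_real_, stable = NA,
                evaluable = FALSE))
  pooled <- sqrt((stats::var(v0) + stats::var(v1)) / 2)
  dd <- if (pooled > 0) (mean(v0) - mean(v1)) / pooled else
    if (mean(v0) == mean(v1)) 0 else Inf
  p <- if (pooled == 0 && mean(v0) == mean(v1)) 1 else
    suppressWarnings(stats::wilcox.test(v0, v1, exact = FALSE)$p.value)
  list(pValue = p, stdDiff = dd, stable = p >= 0.05 && abs(dd) < 0.5,
       evaluable = TRUE)
}

#' Screen parameters for correlation with activation time
#'
#' For every parameter x channel, the Spearman rank correlation of
#' per-cell values against activation time over the activated (`ACT`)
#' groups is computed; p-values are Benjamini-Hochberg adjusted across all
#' parameter x channel tests.  A parameter is selected when the adjusted
#' p-value is below `fdr`, |rho| is at least `rhoGate`, and it passes the
#' control-stability gate.  Constant parameters are excluded with a note.
#'
#' @param se a `SummarizedExperiment` from [seriesParameters()]
#' @param fdr false-discovery-rate level (default 0.05)
#' @param rhoGate minimum |Spearman rho| (default 0.5)
#' @param requireStable gate on [controlStability()] (default TRUE)
#' @return A data.frame with one row per parameter x channel: `rho`,
#'   `pValue`, `pAdjusted`, `stable`, `selected`, `direction` and `note`.
#' @export
screenCorrelation <- function(se, fdr = 0.05, rhoGate = 0.5,
                              requireStable = TRUE) {
  x <- .assayLong(se)
  act <- grepl("^ACT", x$cd$group)
  if (length(unique(x$cd$timeMin[act])) < 3)
    stop("need at least 3 activation time points")
  channels <- unique(x$cd$channel)
  rows <- list()
  for (ch in channels) {
    sel <- act & x$cd$channel == ch
    tv <- x$cd$timeMin[sel]
    for (par in rownames(x$mat)) {
      y <- x$mat[par, sel]
      note <- NA_character_
      if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0) {
        rho <- NA_real_; p <- NA_real_
        note <- "constant or undefined parameter, excluded"
      } else {
        ct <- suppressWarnings(
          stats::cor.test(tv, y, method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, channel = ch, rho = rho, pValue = p,
        note = note, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$pAdjusted <- stats::p.adjust(res$pValue, method = "BH")
  res$stable <- vapply(seq_len(nrow(res)), function(i) {
    st <- controlStability(se, res$parameter[i], res$channel[i])
    isTRUE(st$stable)
  }, logical(1))
  res$selected <- !is.na(res$pAdjusted) & res$pAdjusted < fdr &
    !is.na(res$rho) & abs(res$rho) >= rhoGate &
    (if (requireStable) res$stable else TRUE)
  res$direction <- ifelse(is.na(res$rho), NA_character_,
                          ifelse(res$rho > 0, "increasing", "decreasing"))
  res[order(res$channel, res$parameter), ]
}

## Extract per-cell (level, value) training points for one parameter.
.calibPoints <- function(se, parameter, channel) {
  x <- .assayLong(se)
  sel <- x$cd$channel == channel
  data.frame(level = x$cd$activationLevel[sel],
             value = as.numeric(x$mat[parameter, sel]))
}

## Monotone (isotonic) curve of value vs level, returned on a level grid.
.isotonicCurve <- function(level, value) {
  ok <- !is.na(value)
  level <- level[ok]; value <- value[ok]
  o <- order(level)
  level <- level[o]; value <- value[o]
  increasing <- suppressWarnings(
    stats::cor(level, value, method = "spearman")) >= 0
  ir <- if (increasing) stats::isoreg(level, value) else
    stats::isoreg(level, -value)
  fit <- if (increasing) ir$yf else -ir$yf
  grid <- sort(unique(level))
  fitted <- vapply(grid, function(g) mean(fit[level == g]), numeric(1))
  resid <- value - stats::approx(grid, fitted, xout = level,
                                 rule = 2)$y
  list(level = grid, fitted = fitted, increasing = increasing,
       residSd = stats::sd(resid))
}

## Invert a monotone curve at a query value (clamped, with flag).
.invertCurve <- function(curve, value) {
  fv <- curve$fitted
  lv <- curve$level
  if (!curve$increasing) { fv <- rev(fv); lv <- rev(lv) }
  ## make strictly increasing for inversion
  o <- order(fv)
  fv <- fv[o]; lv <- lv[o]
  keep <- !duplicated(fv)
  fv <- fv[keep]; lv <- lv[keep]
  extrapolated <- value < min(fv) || value > max(fv)
  if (length(fv) < 2)
    return(list(level = lv[1], extrapolated = TRUE))
  est <- stats::approx(fv, lv, xout = clamp(value, min(fv), max(fv)),
                       rule = 2)$y
  list(level = clamp(est, 0, 1), extrapolated = extrapolated)
}

#' Fit a monotone activation calibration
#'
#' Fits isotonic regressions of the chosen restored-adhesion-channel
#' parameters (Srwi increases and Shw decreases with activation, so both
#' admit monotone inversion; Stdi is deliberately excluded because its
#' time course is not monotone at late times) against the latent
#' activation level, together with bootstrap replicates (resampling cells
#' within groups) for interval estimation.
#'
#' @param se a training `SummarizedExperiment` from [seriesParameters()]
#' @param parameters parameters to calibrate on (default Srwi, Shw)
#' @param channel calibration channel (default restored adhesion)
#' @param nBoot bootstrap replicates (default 200)
#' @param tau saturation constant used to translate level to minutes
#' @param seed seed for the bootstrap resampling
#' @return An [ActivationCalibration].
#' @export
fitActivationCalibration <- function(se, parameters = c("Srwi", "Shw"),
                                     channel = "restored adhesion",
                                     nBoot = 200, tau = 10, seed = 1) {
  curves <- lapply(parameters, function(p)
    .isotonicCurve(.calibPoints(se, p, channel)$level,
                   .calibPoints(se, p, channel)$value))
  names(curves) <- parameters
  x <- .assayLong(se)
  sel <- which(x$cd$channel == channel)
  grp <- x$cd$group[sel]
  boot <- withSeed(seed, {
    lapply(seq_len(nBoot), function(b) {
      idx <- unlist(lapply(unique(grp), function(g) {
        i <- sel[grp == g]
        sample(i, length(i), replace = TRUE)
      }))
      lapply(parameters, function(p)
        .isotonicCurve(x$cd$activationLevel[idx],
                       as.numeric(x$mat[p, idx])))
    })
  })
  boot <- lapply(boot, function(b) stats::setNames(b, parameters))
  new("ActivationCalibration",
      parameters = parameters, channel = channel, curves = curves,
      bootCurves = boot,
      residSd = vapply(curves, function(cu) cu$residSd, numeric(1)),
      tau = tau)
}

#' Estimate the activation level from restored-adhesion parameters
#'
#' Inverts each calibrated monotone curve at the queried parameter value,
#' combines the per-parameter levels by inverse-variance weighting (the
#' variances taken from the bootstrap replicates) and reports a bootstrap
#' percentile interval.  Queries outside the calibration range are
#' clamped and flagged as extrapolated.
#'
#' @param params named numeric vector holding at least the calibrated
#'   parameters (e.g. a [parameterSuite()] result for a
#'   restored-adhesion map)
#' @param calibration an [ActivationCalibration]
#' @param level confidence level of the interval (default 0.95)
#' @return A list with `level`, `interval` (length 2), `perParameter`,
#'   `extrapolated` and `timeMin` (the level mapped to minutes via the
#'   saturating curve).
#' @export
estimateActivation <- function(params, calibration, level = 0.95) {
  stopifnot(is(calibration, "ActivationCalibration"))
  pars <- calibration@parameters
  if (!all(pars %in% names(params)))
    stop("params must contain: ", paste(pars, collapse = ", "))
  inv <- lapply(pars, function(p)
    .invertCurve(calibration@curves[[p]], params[[p]]))
  names(inv) <- pars
  bootLevels <- vapply(calibration@bootCurves, function(b) {
    est <- vapply(pars, function(p)
      .invertCurve(b[[p]], params[[p]])$level, numeric(1))
    mean(est)
  }, numeric(1))
  perVar <- vapply(pars, function(p) {
    v <- vapply(calibration@bootCurves, function(b)
      .invertCurve(b[[p]], params[[p]])$level, numeric(1))
    stats::var(v)
  }, numeric(1))
  w <- 1 / pmax(perVar, 1e-6)
  perLevel <- vapply(inv, function(i) i$level, numeric(1))
  est <- sum(w * perLevel) / sum(w)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(bootLevels, c(alpha, 1 - alpha),
                               na.rm = TRUE))
  list(level = est, interval = ci, perParameter = perLevel,
       extrapolated = any(vapply(inv, function(i) i$extrapolated,
                                 logical(1))),
       timeMin = levelToMinutes(est, calibration@tau))
}

#' Permutation null of the correlation screen
#'
#' Randomly permutes the activation-time labels of the activated cells
#' and re-runs the correlation part of the screen, reporting how often
#' any parameter x channel would be selected (Benjamini-Hochberg adjusted
#' p below `fdr` and |rho| at or above `rhoGate`).  A well-calibrated
#' screen selects nothing in the large majority of permutation
#' replicates.
#'
#' @param se a `SummarizedExperiment` from [seriesParameters()]
#' @param nPerm number of permutation replicates (default 100)
#' @param fdr,rhoGate screen gates, as in [screenCorrelation()]
#' @param seed seed for the permutations
#' @return A list with `emptyFraction` (fraction of replicates selecting
#'   nothing) and `selectedCounts` (per-replicate selection counts).
#' @export
permutationNull <- function(se, nPerm = 100, fdr = 0.05, rhoGate = 0.5,
                            seed = 1) {
  x <- .assayLong(se)
  act <- grepl("^ACT", x$cd$group)
  channels <- unique(x$cd$channel)
  ## per channel: rank-transform the parameter values once
  ranked <- list()
  for (ch in channels) {
    sel <- act & x$cd$channel == ch
    sub <- x$mat[, sel, drop = FALSE]
    keep <- apply(sub, 1, function(y) !all(is.na(y)) && stats::sd(y) > 0)
    ranked[[ch]] <- list(
      r = t(apply(sub[keep, , drop = FALSE], 1, rank)),
      time = x$cd$timeMin[sel])
  }
  counts <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    nsel <- 0L
    ps <- c(); rhos <- c()
    for (ch in channels) {
      rk <- ranked[[ch]]
      tp <- sample(rk$time)
      tr <- rank(tp)
      n <- length(tr)
      rho <- as.numeric(stats::cor(t(rk$r), tr))
      tt <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      ps <- c(ps, p); rhos <- c(rhos, rho)
    }
    padj <- stats::p.adjust(ps, method = "BH")
    sum(padj < fdr & abs(rhos) >= rhoGate)
  }, integer(1)))
  list(emptyFraction = mean(counts == 0), selectedCounts = counts)
}

#' Plot parameter trends across the activation series
#'
#' Group-wise boxplots of one parameter per channel, in publication style
#' (controls first, activated groups in time order).
#'
#' @param se a `SummarizedExperiment` from [seriesParameters()]
#' @param parameter parameter name
#' @param channels channels to draw (default: all present)
#' @return Invisibly, the per-group value list.
#' @export
plotParameterTrends <- function(se, parameter, channels = NULL) {
  x <- .assayLong(se)
  if (is.null(channels)) channels <- unique(x$cd$channel)
  ord <- order(!grepl("^CTR", x$cd$group), x$cd$timeMin)
  groups <- unique(x$cd$group[ord])
  old <- graphics::par(mfrow = c(1, length(channels)),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  res <- list()
  for (ch in channels) {
    vals <- lapply(groups, function(g)
      x$mat[parameter, x$cd$group == g & x$cd$channel == ch])
    names(vals) <- groups
    graphics::boxplot(vals, las = 2, main = ch, ylab = parameter)
    res[[ch]] <- vals
  }
  invisible(res)
}
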