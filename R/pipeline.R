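## End-to-end pipeline driver behind the command-line interface.

#' Run the synthetic activation study end to end
#'
#' Drives the full pipeline from a validated configuration: simulate the
#' activation series, (for `calibrate`) calibrate a cantilever on
#' synthetic thermal noise, compute QC reports and the parameter suite,
#' run the correlation screen and fit/apply the activation-level
#' estimator.  All outputs are deterministic for a fixed seed; a
#' structured plain-text log (stage, seed, versions) is written alongside
#' the outputs.
#'
#' @param config a `PipelineConfig` from [readPipelineConfig()], or a
#'   path to a YAML configuration file
#' @param stage one of `"simulate-series"`, `"calibrate"`, `"qc"`,
#'   `"params"`, `"screen"`, `"estimate"`, `"all"`
#' @param outDir output directory (overrides the configuration)
#' @return Invisibly, a list of computed objects (series, parameter
#'   `SummarizedExperiment`, screen table, calibration, estimates) for
#'   the stages run.
#' @export
runPipeline <- function(config, stage = "all", outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stage <- match.arg(stage, c("simulate-series", "calibrate", "qc",
                              "params", "screen", "estimate", "all"))
  outDir <- outDir %||% config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  logPath <- file.path(outDir, "pipeline-log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logPath, append = TRUE)
  cat(sprintf("# afmring pipeline log\n# R %s, afmring %s\n# seed = %d\n",
              getRversion(),
              as.character(utils::packageVersion("afmring")), seed),
      file = logPath)
  res <- list()
  sCfg <- .configSurface(config)
  ser <- config$series %||% list()
  times <- ser$times_min %||% c(5, 10, 30, 60, 120)
  nCells <- ser$n_cells %||% 20
  tau <- ser$tau_min %||% 10

  needSeries <- stage %in% c("simulate-series", "qc", "params", "screen",
                             "estimate", "all")
  if (needSeries) {
    logLine("stage simulate-series: times = %s, nCells = %d, tau = %g",
            paste(times, collapse = ","), nCells, tau)
    res$series <- generateActivationSeries(times = times, nCells = nCells,
                                           base = sCfg, tau = tau,
                                           seed = seed)
    if (stage %in% c("simulate-series", "all"))
      writeActivationSeries(res$series, file.path(outDir, "maps"))
  }
  if (stage %in% c("calibrate", "all")) {
    logLine("stage calibrate: thermal PSD spring-constant calibration")
    rCfg <- .configRinging(config)
    th <- generateThermalTrace(rCfg, 295, duration = 2^18 / rCfg@samplingRate,
                               seed = deriveSeed(seed, 5L))
    res$calibration <- fitSpringConstantPSD(th)
    writeCalibrationReport(res$calibration,
                           file.path(outDir, "calibration.txt"))
  }
  if (stage %in% c("qc", "params", "screen", "estimate", "all")) {
    logLine("stage qc: screening %d maps", nrow(seriesManifest(res$series)))
    qcThr <- list(
      lineArtifact = config$qc$line_artifact %||% 1.0,
      spikeFraction = config$qc$spike_fraction %||% 0.01,
      saturationFraction = config$qc$saturation_fraction %||% 0.001)
    man <- seriesManifest(res$series)
    qc <- vapply(man$mapId, function(id)
      screenMap(seriesMaps(res$series)[[id]], qcThr)@passed, logical(1))
    res$qc <- data.frame(mapId = man$mapId, passed = qc)
    utils::write.csv(res$qc, file.path(outDir, "qc.csv"),
                     row.names = FALSE)
  }
  if (stage %in% c("params", "screen", "estimate", "all")) {
    logLine("stage params: 37-parameter suite per map")
    sp <- config$spectrum %||% list()
    res$parameters <- seriesParameters(
      res$series,
      nLines = sp$n_lines,
      halfFactor = sp$half_factor %||% TRUE,
      binning = sp$binning %||% "sector")
    tidy <- .tidyParameters(res$parameters)
    utils::write.csv(tidy, file.path(outDir, "parameters.csv"),
                     row.names = FALSE)
  }
  if (stage %in% c("screen", "estimate", "all")) {
    logLine("stage screen: Spearman/BH correlation screen")
    sc <- config$screen %||% list()
    res$screen <- screenCorrelation(res$parameters,
                                    fdr = sc$fdr %||% 0.05,
                                    rhoGate = sc$rho_gate %||% 0.5)
    utils::write.csv(res$screen, file.path(outDir, "screen.csv"),
                     row.names = FALSE)
  }
  if (stage %in% c("estimate", "all")) {
    logLine("stage estimate: monotone activation calibration")
    res$activationCalibration <- fitActivationCalibration(
      res$parameters, tau = tau, seed = deriveSeed(seed, 9L))
    x <- .assayLong(res$parameters)
    sel <- x$cd$channel == "restored adhesion"
    est <- lapply(which(sel), function(i)
      estimateActivation(x$mat[, i], res$activationCalibration))
    res$estimates <- data.frame(
      mapId = colnames(x$mat)[sel], group = x$cd$group[sel],
      trueLevel = x$cd$activationLevel[sel],
      estimatedLevel = vapply(est, `[[`, numeric(1), "level"),
      lower = vapply(est, function(e) e$interval[1], numeric(1)),
      upper = vapply(est, function(e) e$interval[2], numeric(1)))
    utils::write.csv(res$estimates, file.path(outDir, "estimates.csv"),
                     row.names = FALSE)
  }
  logLine("done")
  invisible(res)
}

## Long-format (map id, channel, parameter, value) parameter table.
.tidyParameters <- function(se) {
  x <- .assayLong(se)
  data.frame(
    map_id = rep(colnames(x$mat), each = nrow(x$mat)),
    channel = rep(x$cd$channel, each = nrow(x$mat)),
    parameter = rep(rownames(x$mat), times = ncol(x$mat)),
    value = as.numeric(x$mat),
    stringsAsFactors = FALSE)
}
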