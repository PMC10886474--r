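## File formats: Gwyddion Simple Field (GSF), CSV map grids, columnar
## force traces, series manifests and the YAML pipeline configuration.

#' Write / read a surface map as Gwyddion Simple Field
#'
#' GSF is Gwyddion's simple single-channel raster format: a magic line,
#' text `key = value` headers (grid size, physical size in metres, units,
#' title), NUL padding to a 4-byte boundary, then 32-bit little-endian
#' floats in row-major order.  The round trip preserves values to float32
#' precision and the pitch/channel/units metadata exactly.
#'
#' @param map a [SurfaceMap]
#' @param path output file path
#' @return `writeGSF` returns `path` invisibly; `readGSF` returns a
#'   [SurfaceMap].
#' @examples
#' f <- tempfile(fileext = ".gsf")
#' writeGSF(generateSurface(surfaceConfig(gridSize = 64), seed = 1), f)
#' readGSF(f)
#' @export
writeGSF <- function(map, path) {
  stopifnot(is(map, "SurfaceMap"))
  m <- nrow(map@values)
  header <- paste0(
    "Gwyddion Simple Field 1.0\n",
    sprintf("XRes = %d\n", m),
    sprintf("YRes = %d\n", m),
    sprintf("XReal = %.10e\n", m * map@pixelPitch * 1e-9),
    sprintf("YReal = %.10e\n", m * map@pixelPitch * 1e-9),
    "XYUnits = m\n",
    sprintf("ZUnits = %s\n", map@units),
    sprintf("Title = %s\n", map@channel))
  raw <- charToRaw(header)
  pad <- 4L - (length(raw) %% 4L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw, con)
  writeBin(raw(pad), con)
  ## row-major: transpose so rows stream consecutively
  writeBin(as.numeric(t(map@values)), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @param path a GSF file
#' @rdname writeGSF
#' @export
readGSF <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  magic <- "Gwyddion Simple Field 1.0\n"
  if (length(raw) < nchar(magic) ||
      rawToChar(raw[seq_len(nchar(magic))]) != magic)
    stop("not a Gwyddion Simple Field file (bad magic line)")
  nulPos <- which(raw == as.raw(0))[1]
  if (is.na(nulPos)) stop("malformed GSF: header terminator not found")
  header <- rawToChar(raw[seq_len(nulPos - 1L)])
  lines <- strsplit(header, "\n")[[1]][-1]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  xres <- as.integer(kv$XRes); yres <- as.integer(kv$YRes)
  if (is.na(xres) || is.na(yres)) stop("malformed GSF: missing XRes/YRes")
  dataStart <- nulPos - 1L
  dataStart <- dataStart + (4L - (dataStart %% 4L))
  expect <- 4L * xres * yres
  if (sz - dataStart < expect)
    stop(sprintf(
      "malformed GSF: expected %d data bytes, found %d (truncated?)",
      expect, sz - dataStart))
  vals <- readBin(raw[(dataStart + 1L):(dataStart + expect)], "numeric",
                  n = xres * yres, size = 4L, endian = "little")
  pitch <- as.numeric(kv$XReal) / xres * 1e9
  surfaceMap(t(matrix(vals, xres, yres)), pixelPitch = pitch,
             channel = kv$Title %||% "height",
             units = kv$ZUnits %||% "nm", provenance = path)
}

#' Write / read a surface map as a CSV grid
#'
#' A plain comma-separated value grid with `#`-prefixed header lines
#' carrying the pixel pitch, channel and units; values round-trip at full
#' double precision.
#'
#' @param map a [SurfaceMap]
#' @param path output file path
#' @return `writeSurfaceCSV` returns `path` invisibly; `readSurfaceCSV`
#'   returns a [SurfaceMap].
#' @export
writeSurfaceCSV <- function(map, path) {
  stopifnot(is(map, "SurfaceMap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_pitch_nm = %.10g", map@pixelPitch),
               sprintf("# channel = %s", map@channel),
               sprintf("# units = %s", map@units)), con)
  utils::write.table(format(map@values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param path a CSV grid file
#' @rdname writeSurfaceCSV
#' @export
readSurfaceCSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getKV <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(".*=", "", hit[1]))
  }
  body <- lines[!grepl("^#", lines)]
  vals <- do.call(rbind, lapply(body[nzchar(body)], function(ln)
    as.numeric(strsplit(ln, ",", fixed = TRUE)[[1]])))
  surfaceMap(vals, pixelPitch = as.numeric(getKV("pixel_pitch_nm", "20")),
             channel = getKV("channel", "height"),
             units = getKV("units", "nm"), provenance = path)
}

#' Write / read a force trace as two-column text
#'
#' Columnar text (`time_s force_nN`) with a `#`-prefixed header carrying
#' the acquisition configuration.
#'
#' @param trace a [ForceTrace]
#' @param path output file path
#' @return `writeForceTrace` returns `path` invisibly; `readForceTrace`
#'   returns a [ForceTrace].
#' @export
writeForceTrace <- function(trace, path) {
  stopifnot(is(trace, "ForceTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# channel = %s", trace@channel),
           sprintf("# units = %s", trace@units))
  cfg <- trace@metadata$truth$config
  if (!is.null(cfg) && is(cfg, "RingingConfig"))
    hdr <- c(hdr,
             sprintf("# spring_constant_N_per_m = %.10g",
                     cfg@springConstant),
             sprintf("# resonance_freq_Hz = %.10g", cfg@resonanceFreq),
             sprintf("# quality_factor = %.10g", cfg@qualityFactor),
             sprintf("# sampling_rate_Hz = %.10g", cfg@samplingRate))
  writeLines(c(hdr, "# time_s force"), con)
  utils::write.table(
    data.frame(sprintf("%.12e", trace@time),
               sprintf("%.12e", trace@force)),
    con, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param path a force-trace text file
#' @rdname writeForceTrace
#' @export
readForceTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getKV <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(".*=", "", hit[1]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  mat <- do.call(rbind, lapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
  forceTrace(mat[, 1], mat[, 2], units = getKV("units", "nN"),
             channel = getKV("channel", "force"))
}

#' Write / read an activation series to a directory
#'
#' Maps are written one file per manifest row (GSF by default, CSV
#' optionally) together with `manifest.csv` (time_min, cell_id, channel,
#' path, group, activation_level).
#'
#' @param series an [ActivationSeries]
#' @param dir output directory (created if needed)
#' @param format `"gsf"` or `"csv"`
#' @return `writeActivationSeries` returns `dir` invisibly;
#'   `readActivationSeries` returns an [ActivationSeries].
#' @export
writeActivationSeries <- function(series, dir, format = c("gsf", "csv")) {
  format <- match.arg(format)
  stopifnot(is(series, "ActivationSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- seriesManifest(series)
  ext <- if (format == "gsf") ".gsf" else ".csv"
  man$path <- file.path(dir, paste0(man$mapId, ext))
  for (i in seq_len(nrow(man))) {
    mp <- seriesMaps(series)[[man$mapId[i]]]
    if (format == "gsf") writeGSF(mp, man$path[i]) else
      writeSurfaceCSV(mp, man$path[i])
  }
  out <- data.frame(time_min = man$timeMin, cell_id = man$cellId,
                    channel = man$channel, path = basename(man$path),
                    group = man$group,
                    activation_level = man$activationLevel,
                    map_id = man$mapId)
  utils::write.csv(out, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @param dir a directory written by `writeActivationSeries`
#' @rdname writeActivationSeries
#' @export
readActivationSeries <- function(dir) {
  manPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manPath)) stop("manifest.csv not found in ", dir)
  man <- utils::read.csv(manPath, stringsAsFactors = FALSE)
  maps <- list()
  for (i in seq_len(nrow(man))) {
    p <- file.path(dir, man$path[i])
    maps[[man$map_id[i]]] <- if (grepl("\\.gsf$", p)) readGSF(p) else
      readSurfaceCSV(p)
  }
  new("ActivationSeries",
      manifest = data.frame(mapId = man$map_id, group = man$group,
                            timeMin = man$time_min, cellId = man$cell_id,
                            channel = man$channel,
                            activationLevel = man$activation_level,
                            stringsAsFactors = FALSE),
      maps = maps)
}

## Known configuration schema: section -> allowed keys.
.configSchema <- list(
  seed = NULL, out_dir = NULL,
  ringing = c("spring_constant_N_per_m", "resonance_freq_Hz",
              "quality_factor", "sampling_rate_Hz",
              "deflection_sensitivity_nm_per_V"),
  surface = c("grid_size", "pixel_pitch_nm", "activation_level",
              "grain_radius_nm", "grain_density_per_um2",
              "fold_wavelength_nm", "fold_anisotropy", "target_rms",
              "noise_sd"),
  series = c("times_min", "n_cells", "tau_min"),
  qc = c("line_artifact", "spike_fraction", "saturation_fraction"),
  spectrum = c("n_lines", "half_factor", "binning"),
  screen = c("fdr", "rho_gate"))

#' Read and validate a pipeline configuration
#'
#' YAML configuration with explicit units in key names; unknown sections
#' or keys are rejected.
#'
#' @param path YAML file path
#' @return A validated configuration list with class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown) > 0)
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .configSchema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "PipelineConfig")
}

## Materialise S4 configs from the configuration list.
.configRinging <- function(cfg) {
  r <- cfg$ringing %||% list()
  ringingConfig(
    springConstant = r$spring_constant_N_per_m %||% 0.4,
    resonanceFreq = r$resonance_freq_Hz %||% 75e3,
    qualityFactor = r$quality_factor %||% 25,
    samplingRate = r$sampling_rate_Hz %||% 2e6,
    deflectionSensitivity = r$deflection_sensitivity_nm_per_V %||% 50)
}

.configSurface <- function(cfg) {
  s <- cfg$surface %||% list()
  surfaceConfig(
    gridSize = s$grid_size %||% 256L,
    pixelPitch = s$pixel_pitch_nm %||% 20,
    activationLevel = s$activation_level %||% 0,
    grainRadius = s$grain_radius_nm %||% 55,
    grainDensity = s$grain_density_per_um2 %||% 120,
    foldWavelength = s$fold_wavelength_nm %||% 650,
    foldAnisotropy = s$fold_anisotropy %||% 0.7,
    targetRms = s$target_rms %||% 0.35,
    noiseSd = s$noise_sd %||% 0.05)
}
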