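# File formats: a flat YAML run configuration, Beckman XL-I-style per-scan
# text files, and a single-CSV scan matrix.  Readers validate invariants on
# load; writers serialise any valid in-memory object.

#' Prediction-run configuration
#'
#' Everything needed to simulate a run: geometry, run conditions,
#' simulation settings, the component list, the loading signal and output
#' options.
#'
#' @slot geometry a \code{CellGeometry}
#' @slot run a \code{RunConditions}
#' @slot settings a \code{SimulationSettings}
#' @slot components list of \code{SoluteComponent}s
#' @slot z0 loading signal
#' @slot output named list of output options (format, smooth, dcdt, dcdr,
#'   replicates)
#' @export
setClass("PredictConfig",
  representation(geometry = "CellGeometry", run = "RunConditions",
                 settings = "SimulationSettings", components = "list",
                 z0 = "numeric", output = "list"))

setValidity("PredictConfig", function(object) {
  msg <- character()
  if (!length(object@components) ||
      !all(vapply(object@components, is, TRUE, class2 = "SoluteComponent")))
    msg <- c(msg, "components must be a non-empty list of SoluteComponent")
  y <- vapply(object@components, function(k) k@signalFraction, 0)
  if (abs(sum(y) - 1) > 1e-6) msg <- c(msg, "signal fractions must sum to 1")
  if (object@z0 <= 0) msg <- c(msg, "z0 must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictConfig", function(object) {
  cat(sprintf("PredictConfig: %d component(s), %g rpm, %.4g s run\n",
              length(object@components), object@run@rpm, object@run@tRun))
})

.configKeys <- c("rpm", "temperature", "t_run", "scan_times", "n_scans",
                 "meniscus", "bottom", "n_part", "n_steps", "n_bins", "seed",
                 "substeps_per_scan", "z0", "components", "output")
.requiredKeys <- c("rpm", "temperature", "t_run", "meniscus", "bottom",
                   "components")

#' Load a prediction configuration
#'
#' Reads a flat YAML file describing instrument, simulation controls and
#' components (keys: rpm, temperature [K], t_run [s], scan_times or n_scans,
#' meniscus, bottom [cm], n_part, n_steps, n_bins, seed, substeps_per_scan,
#' z0, components [list of \{s, mb, y\}], output).  Unknown keys warn;
#' missing required keys raise an error naming them.  Signal fractions that
#' do not sum to 1 are renormalised with a warning.
#'
#' @param path configuration file
#' @return a \code{PredictConfig}
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config is not a key-value mapping: ", path)
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.requiredKeys, names(cfg))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  geometry <- CellGeometry(cfg$meniscus, cfg$bottom)
  tRun <- as.numeric(cfg$t_run)
  scanTimes <- if (!is.null(cfg$scan_times)) as.numeric(cfg$scan_times)
    else seq(0, tRun, length.out = if (!is.null(cfg$n_scans))
      as.integer(cfg$n_scans) else 11)
  run <- RunConditions(cfg$rpm, as.numeric(cfg$temperature), tRun, scanTimes)
  settings <- SimulationSettings(
    nPart = if (!is.null(cfg$n_part)) cfg$n_part else 1e6,
    nSteps = if (!is.null(cfg$n_steps)) cfg$n_steps else 100,
    nBins = if (!is.null(cfg$n_bins)) cfg$n_bins else 100,
    seed = if (!is.null(cfg$seed)) cfg$seed else 1,
    substepsPerScan = if (!is.null(cfg$substeps_per_scan))
      cfg$substeps_per_scan else 1)
  comps <- cfg$components
  if (!is.list(comps) || !length(comps)) stop("components must be a list")
  # YAML 1.1 parses a bare `y` key as the boolean TRUE; map it back
  comps <- lapply(comps, function(k) {
    names(k)[names(k) == "TRUE"] <- "y"
    k
  })
  y <- vapply(comps, function(k) {
    if (is.null(k$y)) stop("component missing key: y")
    as.numeric(k$y)
  }, 0)
  if (abs(sum(y) - 1) > 1e-6) {
    warning(sprintf("signal fractions sum to %.6g; renormalising", sum(y)))
  }
  y <- y / sum(y)
  components <- lapply(seq_along(comps), function(i) {
    k <- comps[[i]]
    for (key in c("s", "mb"))
      if (is.null(k[[key]])) stop("component ", i, " missing key: ", key)
    SoluteComponent(s = as.numeric(k$s), buoyantMw = as.numeric(k$mb),
                    signalFraction = y[i])
  })
  new("PredictConfig", geometry = geometry, run = run, settings = settings,
      components = components,
      z0 = if (!is.null(cfg$z0)) as.numeric(cfg$z0) else 1,
      output = if (!is.null(cfg$output)) cfg$output else list())
}

#' Write a scan set as XL-I-style scan files
#'
#' One text file per scan (\code{00001.ra1}, ...): line 1 a free-text
#' description; line 2 the header "R <cell> <temp degC> <rpm> <elapsed s>
#' <omega^2 t>"; then two whitespace-separated columns, radius (cm, 5
#' decimals) and signal (6 decimals).  Requires run conditions in the scan
#' set's metadata for the header.
#'
#' @param scanSet a \code{ScanSet} with run metadata
#' @param directory output directory (created if needed)
#' @param description free-text first line
#' @param cell cell number for the header
#' @return invisibly, the written file paths
#' @export
writeScansXLI <- function(scanSet, directory,
                          description = "simulated sedimentation scan",
                          cell = 1) {
  run <- scanRun(scanSet)
  if (is.null(run)) stop("scan set has no run conditions metadata")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  radii <- scanRadii(scanSet)
  z <- signalMatrix(scanSet)
  tt <- scanTimes(scanSet)
  omega2 <- rpmToOmega(run@rpm)^2
  tempC <- run@temperatureK - 273.15
  paths <- vapply(seq_along(tt), function(j) {
    path <- file.path(directory, sprintf("%05d.ra1", j))
    header <- sprintf("R %d %.1f %d %d %.5e", as.integer(cell), tempC,
                      as.integer(round(run@rpm)),
                      as.integer(round(tt[j])), omega2 * tt[j])
    body <- sprintf("%.5f %.6f", radii, z[, j])
    writeLines(c(description, header, body), path)
    path
  }, "")
  invisible(paths)
}

#' Read XL-I-style scan files
#'
#' Reads every \code{*.ra1} (or, failing that, every regular) file in the
#' directory, checks header consistency (rpm, temperature, radii must agree
#' across scans) and assembles a \code{ScanSet} ordered by elapsed time.
#' A trailing third data column, present in some instrument dialects, is
#' ignored.
#'
#' @param directory directory of scan files
#' @param z0 loading signal to record (default 1)
#' @return a \code{ScanSet} (geometry metadata is not recoverable from the
#'   files and is left unset)
#' @export
readScansXLI <- function(directory, z0 = 1) {
  if (!dir.exists(directory)) stop("not a directory: ", directory)
  files <- list.files(directory, pattern = "\\.ra1$", full.names = TRUE)
  if (!length(files)) files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no scan files in ", directory)
  scans <- lapply(sort(files), readOneXLI)
  rpm <- unique(vapply(scans, `[[`, 0, "rpm"))
  if (length(rpm) != 1)
    stop("inconsistent rotor speed across scans: ",
         paste(rpm, collapse = ", "))
  tempC <- unique(vapply(scans, `[[`, 0, "tempC"))
  if (length(tempC) != 1)
    stop("inconsistent temperature across scans")
  radii <- scans[[1]]$radii
  for (s in scans[-1])
    if (length(s$radii) != length(radii) || max(abs(s$radii - radii)) > 5e-6)
      stop("inconsistent radial grids across scans in ", directory)
  ord <- order(vapply(scans, `[[`, 0, "time"))
  scans <- scans[ord]
  tt <- vapply(scans, `[[`, 0, "time")
  z <- do.call(cbind, lapply(scans, `[[`, "signal"))
  run <- RunConditions(rpm, tempC + 273.15, tRun = max(tt, 1), scanTimes = tt)
  ScanSet(radii, tt, z, z0 = z0, run = run)
}

readOneXLI <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed scan file (too short): ", path)
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(hdr) < 6 || hdr[1] != "R")
    stop("malformed header in ", path, " line 2")
  num <- suppressWarnings(as.numeric(hdr[2:6]))
  if (any(is.na(num)))
    stop("malformed header in ", path, " line 2")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop("malformed data line in ", path, " line ", bad[1] + 2)
  radii <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  sig <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(radii)) || any(is.na(sig))) {
    bad <- which(is.na(radii) | is.na(sig))[1]
    stop("malformed data line in ", path, " line ", bad + 2)
  }
  list(tempC = num[2], rpm = num[3], time = num[4], radii = radii,
       signal = sig)
}

#' Write / read a scan set as a single CSV matrix
#'
#' First column \code{radius}; one column per scan whose header is the scan
#' time in seconds.  Values are written with full double precision, so the
#' round trip is exact.
#'
#' @param scanSet a \code{ScanSet}
#' @param path file path
#' @return \code{writeScansCSV}: the path, invisibly; \code{readScansCSV}:
#'   a \code{ScanSet}
#' @export
writeScansCSV <- function(scanSet, path) {
  radii <- scanRadii(scanSet)
  z <- signalMatrix(scanSet)
  tt <- scanTimes(scanSet)
  header <- paste(c("radius", sprintf("%.17g", tt)), collapse = ",")
  rows <- vapply(seq_along(radii), function(i)
    paste(sprintf("%.17g", c(radii[i], z[i, ])), collapse = ","), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname writeScansCSV
#' @param z0 loading signal to record (default 1)
#' @export
readScansCSV <- function(path, z0 = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) stop("CSV must have a radius column and >= 1 scan")
  tt <- as.numeric(colnames(tab)[-1])
  if (any(is.na(tt))) stop("scan-time header is not numeric")
  if (length(tt) > 1 && any(diff(tt) <= 0))
    stop("scan times in header must be increasing")
  radii <- tab[[1]]
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  ScanSet(radii, tt, as.matrix(tab[, -1, drop = FALSE]), z0 = z0)
}

#' Add Gaussian measurement noise to a scan set
#'
#' Adds i.i.d. Gaussian noise of standard deviation \code{sigma} (signal
#' units) to every point, clips at zero, and records sigma and the seed in
#' the metadata.  Used to emulate detector noise on synthetic data.
#'
#' @param scanSet a \code{ScanSet}
#' @param sigma noise standard deviation, signal units (>= 0)
#' @param seed RNG seed
#' @return a \code{ScanSet}
#' @export
addMeasurementNoise <- function(scanSet, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(scanSet)
  z <- signalMatrix(scanSet)
  set.seed(seed)
  z <- pmax(z + rnorm(length(z), sd = sigma), 0)
  out <- scanSet
  SummarizedExperiment::assay(out, "signal") <- z
  metadata(out)$noiseSigma <- sigma
  metadata(out)$noiseSeed <- seed
  out
}

#' @importFrom utils read.csv
NULL
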