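#' Create a solute component
#'
#' Either give \code{buoyantMw} directly, or give \code{mw}, \code{vbar} and
#' \code{rho} and let the buoyant molecular weight be computed as
#' M(1 - v-bar rho).
#'
#' @param s sedimentation coefficient, Svedberg
#' @param buoyantMw buoyant molecular weight, Da (optional if mw/vbar/rho
#'   are given)
#' @param signalFraction fraction of the loading signal contributed by this
#'   component, in (0, 1]
#' @param q,alpha,c0,mw,vbar,rho optional signal/composition provenance; see
#'   \code{\linkS4class{SoluteComponent}}
#' @return a \code{SoluteComponent}
#' @examples
#' lys <- SoluteComponent(s = 1.91, buoyantMw = 4250, signalFraction = 0.65)
#' @export
SoluteComponent <- function(s, buoyantMw = NULL, signalFraction = 1,
                            q = NA_real_, alpha = NA_real_, c0 = NA_real_,
                            mw = NA_real_, vbar = NA_real_, rho = NA_real_) {
  if (is.null(buoyantMw)) {
    if (any(is.na(c(mw, vbar, rho))))
      stop("give buoyantMw, or all of mw, vbar and rho")
    buoyantMw <- buoyantMass(mw, vbar, rho)
  }
  new("SoluteComponent", s = as.numeric(s), buoyantMw = as.numeric(buoyantMw),
      signalFraction = as.numeric(signalFraction), q = q, alpha = alpha,
      c0 = c0, mw = mw, vbar = vbar, rho = rho)
}

#' Create a cell geometry
#' @param rm meniscus radius, cm
#' @param rb bottom radius, cm
#' @export
CellGeometry <- function(rm, rb)
  new("CellGeometry", rm = as.numeric(rm), rb = as.numeric(rb))

#' Create run conditions
#' @param rpm rotor speed, rev/min
#' @param temperatureK absolute temperature, K
#' @param tRun run duration, s
#' @param scanTimes scan times, s; default 11 scans evenly spaced over
#'   [0, tRun]
#' @export
RunConditions <- function(rpm, temperatureK = 293.15, tRun,
                          scanTimes = seq(0, tRun, length.out = 11)) {
  new("RunConditions", rpm = as.numeric(rpm),
      temperatureK = as.numeric(temperatureK), tRun = as.numeric(tRun),
      scanTimes = as.numeric(scanTimes))
}

#' Create simulation settings
#' @param nPart total particle count
#' @param nSteps number of base time steps
#' @param nBins number of radial bins
#' @param seed RNG seed
#' @param substepsPerScan subdivision of each step interval
#' @export
SimulationSettings <- function(nPart = 1e6, nSteps = 100, nBins = 100,
                               seed = 1, substepsPerScan = 1) {
  new("SimulationSettings", nPart = as.numeric(nPart),
      nSteps = as.numeric(nSteps), nBins = as.numeric(nBins),
      seed = as.numeric(seed), substepsPerScan = as.numeric(substepsPerScan))
}

#' Create a scan set
#'
#' @param radii radial bin midpoints, cm (strictly increasing)
#' @param times scan times, s
#' @param z signal matrix, length(radii) x length(times)
#' @param z0 loading signal (default 1; profiles are z relative to loading)
#' @param geometry optional \code{CellGeometry}
#' @param run optional \code{RunConditions}
#' @param metadata additional metadata entries (named list)
#' @export
ScanSet <- function(radii, times, z, z0 = 1, geometry = NULL, run = NULL,
                    metadata = list()) {
  z <- as.matrix(z)
  dimnames(z) <- list(sprintf("r%04d", seq_along(radii)),
                      sprintf("scan%03d", seq_along(times)))
  md <- c(list(z0 = z0, geometry = geometry, run = run), metadata)
  se <- SummarizedExperiment(
    assays = list(signal = z),
    rowData = DataFrame(radius = as.numeric(radii)),
    colData = DataFrame(time = as.numeric(times),
                        row.names = colnames(z)),
    metadata = md)
  new("ScanSet", se)
}

#' Create an experiment for global fitting
#' @param scanSet observed \code{ScanSet} carrying geometry and run metadata
#' @param weight statistical weight (normalised over the experiment list)
#' @param nSteps base time steps for fit-time re-simulation
#' @export
SedExperiment <- function(scanSet, weight = 1, nSteps = 100)
  new("SedExperiment", scanSet = scanSet, weight = as.numeric(weight),
      nSteps = as.numeric(nSteps))

# ---- accessors ----

#' Scan-set accessors
#'
#' @param x a \code{ScanSet}
#' @return \code{scanRadii}: radial bin midpoints (cm); \code{scanTimes}:
#'   scan times (s); \code{signalMatrix}: the signal matrix;
#'   \code{loadingSignal}: z0; \code{scanGeometry} / \code{scanRun}: the
#'   stored geometry / run conditions (or NULL).
#' @export
scanRadii <- function(x) rowData(x)$radius

#' @rdname scanRadii
#' @export
scanTimes <- function(x) colData(x)$time

#' @rdname scanRadii
#' @export
signalMatrix <- function(x) assay(x, "signal")

#' @rdname scanRadii
#' @export
loadingSignal <- function(x) metadata(x)$z0

#' @rdname scanRadii
#' @export
scanGeometry <- function(x) metadata(x)$geometry

#' @rdname scanRadii
#' @export
scanRun <- function(x) metadata(x)$run

#' Fit-result accessors
#' @param x a \code{SedFitResult}
#' @return \code{fitComponents}: list of fitted \code{SoluteComponent}s;
#'   \code{fitDelta2}: the global square deviation; \code{fitConverged}:
#'   logical flag.
#' @export
fitComponents <- function(x) x@components

#' @rdname fitComponents
#' @export
fitDelta2 <- function(x) x@delta2

#' @rdname fitComponents
#' @export
fitConverged <- function(x) x@converged

# ---- show methods ----

setMethod("show", "SoluteComponent", function(object) {
  cat(sprintf("SoluteComponent: s = %.4g S, M^b = %.6g Da, y = %.4g (D = %.4g cm^2/s at 293.15 K)\n",
              object@s, object@buoyantMw, object@signalFraction,
              diffusionCoefficient(object@s, object@buoyantMw, 293.15)))
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry: meniscus %.4g cm, bottom %.4g cm\n",
              object@rm, object@rb))
})

setMethod("show", "RunConditions", function(object) {
  cat(sprintf("RunConditions: %g rpm, %.2f K, %.4g s run, %d scans\n",
              object@rpm, object@temperatureK, object@tRun,
              length(object@scanTimes)))
})

setMethod("show", "ScanSet", function(object) {
  r <- scanRadii(object)
  cat(sprintf("ScanSet: %d radial bins [%.4g, %.4g] cm x %d scans, z0 = %g\n",
              length(r), r[1], r[length(r)], ncol(object),
              loadingSignal(object)))
})

setMethod("show", "SedFitResult", function(object) {
  cat(sprintf("SedFitResult: %d component(s), Delta^2 = %.4g, %s after %d evaluations\n",
              length(object@components), object@delta2,
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
  for (k in object@components) show(k)
})

setMethod("show", "BoundaryTrack", function(object) {
  cat(sprintf("BoundaryTrack: %d scans", length(object@times)))
  if (!is.na(object@estimatedS))
    cat(sprintf(", s = %.4g +/- %.2g S", object@estimatedS, object@sStdError))
  cat("\n")
})
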