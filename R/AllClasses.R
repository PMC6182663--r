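#' @import methods
#' @importFrom stats median optim rnorm runif sd setNames lm coef vcov
#'   qchisq pchisq
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom Rcpp evalCpp
#' @useDynLib sedbd, .registration = TRUE
NULL

# Physical constants (SI). Fixed, not configurable.
.R_GAS <- 8.314        # J mol^-1 K^-1
.KB <- 1.380649e-23    # J K^-1
.SVEDBERG <- 1e-13     # s

#' One solute species
#'
#' A non-interacting solute component is characterised by its sedimentation
#' coefficient \code{s} (Svedberg), buoyant molecular weight
#' \code{buoyantMw} = M(1 - v-bar rho) (Da) and its fractional contribution
#' \code{signalFraction} to the initially uniform detector signal.  The
#' diffusion coefficient is not an independent property: it follows from the
#' Svedberg relation D = R T s / M^b (see \code{\link{diffusionCoefficient}}).
#'
#' Optional slots record how the signal fraction arises: specific signal
#' constant \code{q}, signal exponent \code{alpha} (0 for mass-proportional
#' detection such as absorbance/interference, 1 for molar-proportional
#' detection), loading concentration \code{c0}, molecular weight \code{mw},
#' partial specific volume \code{vbar} (cm^3/g) and solvent density
#' \code{rho} (g/cm^3).
#'
#' @slot s sedimentation coefficient, Svedberg (1 S = 1e-13 s)
#' @slot buoyantMw buoyant molecular weight, Da
#' @slot signalFraction fraction of the loading signal, in (0, 1]
#' @slot q,alpha,c0,mw,vbar,rho optional provenance of the signal fraction
#'   (NA when unused)
#' @export
setClass("SoluteComponent",
  representation(s = "numeric", buoyantMw = "numeric",
                 signalFraction = "numeric",
                 q = "numeric", alpha = "numeric", c0 = "numeric",
                 mw = "numeric", vbar = "numeric", rho = "numeric"),
  prototype(signalFraction = 1, q = NA_real_, alpha = NA_real_,
            c0 = NA_real_, mw = NA_real_, vbar = NA_real_, rho = NA_real_))

setValidity("SoluteComponent", function(object) {
  msg <- character()
  if (length(object@s) != 1 || !is.finite(object@s) || object@s <= 0)
    msg <- c(msg, "s must be a single positive number (Svedberg)")
  if (length(object@buoyantMw) != 1 || !is.finite(object@buoyantMw) ||
      object@buoyantMw <= 0)
    msg <- c(msg, "buoyantMw must be a single positive number (Da)")
  y <- object@signalFraction
  if (length(y) != 1 || !is.finite(y) || y <= 0 || y > 1)
    msg <- c(msg, "signalFraction must lie in (0, 1]")
  if (!is.na(object@alpha) && !object@alpha %in% c(0, 1))
    msg <- c(msg, "alpha must be 0 or 1")
  if (!is.na(object@mw) && !is.na(object@vbar) && !is.na(object@rho)) {
    mb <- object@mw * (1 - object@vbar * object@rho)
    if (abs(mb - object@buoyantMw) > 1e-9 * abs(mb))
      msg <- c(msg, "buoyantMw inconsistent with mw * (1 - vbar * rho)")
  }
  if (length(msg)) msg else TRUE
})

#' Sector-cell geometry
#'
#' Radial bounds of the solution column: meniscus \code{rm} and bottom
#' \code{rb}, in cm from the rotation axis.
#'
#' @slot rm meniscus radius, cm
#' @slot rb bottom radius, cm
#' @export
setClass("CellGeometry", representation(rm = "numeric", rb = "numeric"))

setValidity("CellGeometry", function(object) {
  if (length(object@rm) != 1 || length(object@rb) != 1 ||
      !is.finite(object@rm) || !is.finite(object@rb) ||
      object@rm <= 0 || object@rb <= object@rm)
    "need 0 < rm < rb (cm)" else TRUE
})

#' Instrument run conditions
#'
#' @slot rpm rotor speed, revolutions per minute
#' @slot temperatureK absolute temperature, K
#' @slot tRun run duration, s
#' @slot scanTimes strictly increasing scan times in [0, tRun], s
#' @export
setClass("RunConditions",
  representation(rpm = "numeric", temperatureK = "numeric",
                 tRun = "numeric", scanTimes = "numeric"))

setValidity("RunConditions", function(object) {
  msg <- character()
  if (object@rpm <= 0) msg <- c(msg, "rpm must be positive")
  if (object@temperatureK <= 0) msg <- c(msg, "temperatureK must be positive")
  if (object@tRun < 0) msg <- c(msg, "tRun must be non-negative")
  st <- object@scanTimes
  if (length(st) < 1 || any(!is.finite(st)) || any(st < 0) ||
      any(diff(st) <= 0))
    msg <- c(msg, "scanTimes must be strictly increasing and non-negative")
  else if (max(st) > object@tRun + 1e-9 * max(object@tRun, 1))
    msg <- c(msg, "scanTimes must not exceed tRun")
  if (length(msg)) msg else TRUE
})

#' Simulation controls
#'
#' @slot nPart total number of simulated particles
#' @slot nSteps number of base time steps of duration tRun/nSteps
#' @slot nBins number of radial bins
#' @slot seed RNG seed
#' @slot substepsPerScan extra subdivision of each step interval (>= 1)
#' @export
setClass("SimulationSettings",
  representation(nPart = "numeric", nSteps = "numeric", nBins = "numeric",
                 seed = "numeric", substepsPerScan = "numeric"),
  prototype(nPart = 1e6, nSteps = 100, nBins = 100, seed = 1,
            substepsPerScan = 1))

setValidity("SimulationSettings", function(object) {
  msg <- character()
  if (object@nPart < 1) msg <- c(msg, "nPart must be >= 1")
  if (object@nSteps < 1) msg <- c(msg, "nSteps must be >= 1")
  if (object@nBins < 2) msg <- c(msg, "nBins must be >= 2")
  if (object@substepsPerScan < 1) msg <- c(msg, "substepsPerScan must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Scan set: signal profiles on a radius x time grid
#'
#' A \code{ScanSet} extends \code{SummarizedExperiment}: rows are radial bin
#' midpoints (rowData column \code{radius}, cm), columns are scans (colData
#' column \code{time}, s), and the single assay \code{"signal"} holds
#' z(r_i, t_j).  The loading signal \code{z0} and, where known, the cell
#' geometry, run conditions and simulation provenance live in
#' \code{metadata()}.
#'
#' @export
setClass("ScanSet", contains = "SummarizedExperiment")

setValidity("ScanSet", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    return("ScanSet needs a 'signal' assay")
  r <- rowData(object)$radius
  tt <- colData(object)$time
  if (is.null(r) || any(!is.finite(r)) || any(diff(r) <= 0))
    msg <- c(msg, "rowData$radius must be strictly increasing and finite")
  if (is.null(tt) || any(!is.finite(tt)) || (length(tt) > 1 && any(diff(tt) <= 0)))
    msg <- c(msg, "colData$time must be strictly increasing and finite")
  z <- assay(object, "signal")
  if (any(!is.finite(z)) || any(z < 0))
    msg <- c(msg, "signal must be finite and non-negative")
  z0 <- metadata(object)$z0
  if (is.null(z0) || !is.finite(z0) || z0 <= 0)
    msg <- c(msg, "metadata z0 must be a positive number")
  geom <- metadata(object)$geometry
  if (!is.null(geom) && is(geom, "CellGeometry")) {
    if (r[1] < geom@rm || r[length(r)] > geom@rb)
      msg <- c(msg, "radii must lie within (rm, rb)")
  }
  if (length(msg)) msg else TRUE
})

#' Smoothed derivatives of a scan set
#'
#' Holds the Savitzky-Golay radial derivative dz/dr on the source grid and
#' the finite-difference time derivative dz/dt reported at scan-interval
#' midpoints, together with the smoothing metadata.
#'
#' @slot radii radial grid, cm
#' @slot times source scan times, s
#' @slot dzdr matrix, signal/cm (same shape as the source signal)
#' @slot midTimes scan-interval midpoints, s (length(times) - 1)
#' @slot dzdt matrix, signal/s, on radii x midTimes
#' @slot window,order Savitzky-Golay window length and polynomial order
#' @export
setClass("DerivativeSet",
  representation(radii = "numeric", times = "numeric", dzdr = "matrix",
                 midTimes = "numeric", dzdt = "matrix",
                 window = "numeric", order = "numeric"))

setValidity("DerivativeSet", function(object) {
  msg <- character()
  if (length(object@window) == 1 && length(object@order) == 1 &&
      (object@window %% 2 != 1 || object@window <= object@order))
    msg <- c(msg, "window must be odd and greater than order")
  if (nrow(object@dzdr) != length(object@radii) ||
      ncol(object@dzdr) != length(object@times))
    msg <- c(msg, "dzdr shape must match radii x times")
  if (length(msg)) msg else TRUE
})

#' Sedimentation-boundary track
#'
#' Per-scan boundary midpoint radii (half-plateau crossings) and the
#' sedimentation coefficient estimated from the slope of ln r vs t.
#'
#' @slot times scan times, s
#' @slot boundaryRadii boundary radii, cm
#' @slot estimatedS estimated sedimentation coefficient, Svedberg (NA until
#'   estimated)
#' @slot sStdError standard error of the estimate, Svedberg
#' @export
setClass("BoundaryTrack",
  representation(times = "numeric", boundaryRadii = "numeric",
                 estimatedS = "numeric", sStdError = "numeric"),
  prototype(estimatedS = NA_real_, sStdError = NA_real_))

setValidity("BoundaryTrack", function(object) {
  if (length(object@times) != length(object@boundaryRadii))
    "times and boundaryRadii must have equal length" else TRUE
})
# NA boundary radii mark scans without a usable plateau; estimates skip them

#' One experiment entering a global fit
#'
#' Bundles an observed \code{ScanSet} (whose metadata must carry geometry and
#' run conditions) with a statistical weight and the number of base time
#' steps used when this experiment is re-simulated during fitting.
#'
#' @slot scanSet observed \code{ScanSet}
#' @slot weight non-negative statistical weight (normalised across the
#'   experiment list before use)
#' @slot nSteps base time steps for fit-time simulation of this experiment
#' @export
setClass("SedExperiment",
  representation(scanSet = "ScanSet", weight = "numeric", nSteps = "numeric"),
  prototype(weight = 1, nSteps = 100))

setValidity("SedExperiment", function(object) {
  msg <- character()
  if (object@weight < 0) msg <- c(msg, "weight must be >= 0")
  if (object@nSteps < 1) msg <- c(msg, "nSteps must be >= 1")
  md <- metadata(object@scanSet)
  if (!is(md$geometry, "CellGeometry"))
    msg <- c(msg, "scanSet metadata must carry a CellGeometry")
  if (!is(md$run, "RunConditions"))
    msg <- c(msg, "scanSet metadata must carry RunConditions")
  if (length(msg)) msg else TRUE
})

#' Result of a global fit
#'
#' @slot components list of fitted \code{SoluteComponent} trios
#' @slot delta2 global square deviation at the final (high-fidelity)
#'   evaluation
#' @slot delta2PerExperiment per-experiment square deviations
#' @slot nIterations simplex function evaluations used
#' @slot converged logical convergence flag
#' @slot history objective value at each simplex evaluation
#' @export
setClass("SedFitResult",
  representation(components = "list", delta2 = "numeric",
                 delta2PerExperiment = "numeric", nIterations = "numeric",
                 converged = "logical", history = "numeric"))

setValidity("SedFitResult", function(object) {
  msg <- character()
  if (!all(vapply(object@components, is, TRUE, class2 = "SoluteComponent")))
    msg <- c(msg, "components must be SoluteComponent objects")
  y <- vapply(object@components, function(k) k@signalFraction, 0)
  if (abs(sum(y) - 1) > 1e-6)
    msg <- c(msg, "signal fractions must sum to 1")
  if (object@delta2 < 0) msg <- c(msg, "delta2 must be >= 0")
  if (length(msg)) msg else TRUE
})
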