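# Closed-form reference profiles: the no-diffusion (infinite-mass) limit and
# the sedimentation-equilibrium (zero-net-flux) limit.  Both serve as
# independent oracles for the particle engine and as quick estimators.

#' No-diffusion sedimentation profile
#'
#' Neglecting diffusion, every particle obeys r(t) = r(0) exp(s w^2 t), so
#' the initially uniform profile becomes a sharp step: zero below the
#' boundary r_bnd = rm exp(s w^2 t) and, by radial dilution in the sector
#' cell, a plateau exp(-2 s w^2 t) above it (equivalently (rm/r_bnd)^2),
#' truncated at the cell bottom.
#'
#' @param component a \code{SoluteComponent} (only s is used)
#' @param geometry a \code{CellGeometry}
#' @param omega angular velocity, rad/s
#' @param t time, s
#' @param radii radii at which to evaluate, cm (default 200 points across
#'   the cell)
#' @return list with \code{radii}, \code{z} (z/z0 values), \code{boundary}
#'   (boundary radius, cm, capped at rb) and \code{plateau}
#' @export
noDiffusionProfile <- function(component, geometry, omega, t,
                               radii = seq(geometry@rm, geometry@rb,
                                           length.out = 200)) {
  stopifnot(t >= 0)
  sw2t <- component@s * .SVEDBERG * omega^2 * t
  rbnd <- geometry@rm * exp(sw2t)
  plateau <- exp(-2 * sw2t)
  z <- ifelse(radii < rbnd, 0, plateau)
  if (rbnd >= geometry@rb) z[] <- 0   # fully pelleted
  list(radii = radii, z = z, boundary = min(rbnd, geometry@rb),
       plateau = plateau)
}

#' Reduced buoyant mass for equilibrium profiles
#'
#' sigma = M^b omega^2 / (R T) in cm^-2; the equilibrium concentration
#' gradient is c(r) proportional to exp(sigma r^2 / 2).
#'
#' @param buoyantMw buoyant molecular weight, Da
#' @param omega angular velocity, rad/s
#' @param temperatureK absolute temperature, K
#' @return sigma, cm^-2
#' @export
equilibriumSigma <- function(buoyantMw, omega, temperatureK) {
  # (kg/mol) rad^2 s^-2 / (J mol^-1) = m^-2; 1e-4 converts to cm^-2
  (buoyantMw * 1e-3) * omega^2 / (.R_GAS * temperatureK) * 1e-4
}

#' Sedimentation-equilibrium profile
#'
#' The zero-net-flux fixed point of sedimentation-diffusion transport:
#' c(r) = A exp(sigma (r^2 - rm^2) / 2) with sigma = M^b w^2 / (R T).  The
#' amplitude A is set so that the sector-weighted integral of c(r) r dr over
#' [rm, rb] equals that of the uniform loading profile (z/z0 = 1), i.e.
#' total signal is conserved.
#'
#' @param component a \code{SoluteComponent} (buoyantMw is used)
#' @param geometry a \code{CellGeometry}
#' @param omega angular velocity, rad/s
#' @param temperatureK absolute temperature, K
#' @param radii evaluation radii, cm
#' @return list with \code{radii}, \code{z} (z/z0), \code{sigma} (cm^-2)
#' @export
equilibriumProfile <- function(component, geometry, omega, temperatureK,
                               radii = seq(geometry@rm, geometry@rb,
                                           length.out = 200)) {
  sigma <- equilibriumSigma(component@buoyantMw, omega, temperatureK)
  rm2 <- geometry@rm^2; rb2 <- geometry@rb^2
  if (sigma < 1e-12) {
    z <- rep(1, length(radii))
  } else {
    # integral of exp(sigma (r^2 - rm^2)/2) r dr = (exp(sigma(rb2-rm2)/2)-1)/sigma
    norm <- (rb2 - rm2) / 2 / ((exp(sigma * (rb2 - rm2) / 2) - 1) / sigma)
    z <- norm * exp(sigma * (radii^2 - rm2) / 2)
  }
  list(radii = radii, z = z, sigma = sigma)
}

#' Expected equilibrium bin fractions
#'
#' Exact sector-weighted integral of the equilibrium profile over each of
#' nBins equal radial bins: the expected fraction of particles per bin, for
#' chi-squared comparison with simulated occupancies.
#'
#' @inheritParams equilibriumProfile
#' @param nBins number of radial bins
#' @return numeric vector of expected fractions summing to 1
#' @export
equilibriumBinFractions <- function(component, geometry, omega, temperatureK,
                                    nBins) {
  sigma <- equilibriumSigma(component@buoyantMw, omega, temperatureK)
  edges <- seq(geometry@rm, geometry@rb, length.out = nBins + 1)
  if (sigma < 1e-12) {
    w <- diff(edges^2)
  } else {
    w <- diff(exp(sigma * edges^2 / 2))
  }
  w / sum(w)
}

#' Estimate s from a boundary track
#'
#' Least-squares slope of ln r_boundary vs t divided by omega^2, converted
#' to Svedberg; the standard error of the slope propagates to the estimate.
#'
#' @param track a \code{BoundaryTrack} (or list with \code{times},
#'   \code{boundaryRadii}) with at least two points
#' @param omega angular velocity, rad/s
#' @return the input \code{BoundaryTrack} with \code{estimatedS} and
#'   \code{sStdError} filled in (Svedberg)
#' @export
estimateSFromBoundary <- function(track, omega) {
  ok <- is.finite(track@boundaryRadii)
  tt <- track@times[ok]; rr <- track@boundaryRadii[ok]
  if (length(tt) < 2) stop("need at least two boundary points")
  fit <- lm(log(rr) ~ tt)
  slope <- coef(fit)[["tt"]]
  # noiseless tracks make the regression exact; the (zero) standard error
  # is still well defined
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[["tt"]])
  track@estimatedS <- slope / omega^2 / .SVEDBERG
  track@sStdError <- se / omega^2 / .SVEDBERG
  track
}

#' Locate the sedimentation boundary in each scan
#'
#' Per scan, the plateau is estimated as the median of z over a window of
#' interior bins ahead of the boundary (by default the last quarter of the
#' interior, clear of the bottom margin); the boundary is the radius where
#' z first crosses half that plateau, by linear interpolation between bins.
#' Scans whose first interior bin already exceeds the half-plateau (e.g.
#' t = 0) report the meniscus-side bin midpoint.  Scans with no flat
#' plateau (relative spread above \code{plateauTol}, e.g. once the boundary
#' or its diffusion tail has entered the window) yield NA; if no scan has a
#' plateau the profiles are not boundary-shaped (equilibrium-type data) and
#' an analysis error is raised.
#'
#' @param scanSet a \code{ScanSet}
#' @param plateauWindow optional integer indices of the plateau bins
#' @param plateauTol maximal allowed IQR/median within the plateau window
#' @param bottomMargin excluded bottom region, cm
#' @return a \code{BoundaryTrack} (without an s estimate; see
#'   \code{\link{estimateSFromBoundary}})
#' @export
locateBoundary <- function(scanSet, plateauWindow = NULL, plateauTol = 0.1,
                           bottomMargin = 0.2) {
  z <- signalMatrix(scanSet) / loadingSignal(scanSet)
  radii <- scanRadii(scanSet)
  geom <- scanGeometry(scanSet)
  if (is.null(plateauWindow)) {
    upper <- if (!is.null(geom)) geom@rb - bottomMargin else
      max(radii) - bottomMargin
    lo <- radii[1] + 0.75 * (upper - radii[1])
    plateauWindow <- which(radii >= lo & radii <= upper)
  }
  if (length(plateauWindow) < 3) stop("plateau window too small")
  bnd <- vapply(seq_len(ncol(z)), function(j) {
    zz <- z[, j]
    pl <- zz[plateauWindow]
    med <- median(pl)
    if (med <= 0 || diff(quantile(pl, c(0.25, 0.75))) > plateauTol * med)
      return(NA_real_)
    h <- med / 2
    below <- which(zz < h)
    below <- below[below < min(plateauWindow)]
    if (!length(below)) return(radii[1])     # boundary at/before meniscus
    i <- max(below)
    if (i >= length(zz)) return(radii[length(radii)])
    # linear interpolation of the crossing between bins i and i+1
    radii[i] + (h - zz[i]) / (zz[i + 1] - zz[i]) * (radii[i + 1] - radii[i])
  }, 0)
  if (all(is.na(bnd)))
    stop("no plateau detectable in any scan: profiles are not ",
         "boundary-shaped")
  new("BoundaryTrack", times = scanTimes(scanSet), boundaryRadii = bnd)
}

#' @importFrom stats quantile
NULL
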