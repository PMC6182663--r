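# Savitzky-Golay post-processing of scan profiles.  The filtering itself is
# delegated to signal::sgolayfilt, whose filter matrix handles the series
# endpoints with one-sided polynomial fits.

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing on a uniform grid.  Reproduces
#' polynomials up to the filter order exactly and attenuates white noise.
#'
#' @param series numeric values on a uniform grid, length >= window
#' @param window odd window length (default 11)
#' @param order polynomial order (default 2), with 0 <= order < window
#' @return smoothed series of the same length
#' @export
savitzkyGolaySmooth <- function(series, window = 11, order = 2) {
  checkSgArgs(length(series), window, order)
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

checkSgArgs <- function(len, window, order) {
  if (window %% 2 != 1) stop("window must be odd")
  if (order < 0 || order >= window) stop("need 0 <= order < window")
  if (len < window) stop("series shorter than the smoothing window")
  invisible(TRUE)
}

#' Radial derivative of a scan set
#'
#' Savitzky-Golay first-derivative filter along the radius, per scan.
#'
#' @param scanSet a \code{ScanSet} (uniform radial grid)
#' @param window,order Savitzky-Golay parameters
#' @return matrix of dz/dr values (signal/cm), same shape as the signal
#' @export
radialDerivative <- function(scanSet, window = 11, order = 2) {
  z <- signalMatrix(scanSet)
  r <- scanRadii(scanSet)
  checkSgArgs(length(r), window, order)
  h <- diff(r)
  if (max(abs(h - h[1])) > 1e-8 * h[1])
    stop("radialDerivative needs a uniform radial grid")
  apply(z, 2, function(col)
    as.numeric(signal::sgolayfilt(col, p = order, n = window, m = 1,
                                  ts = h[1])))
}

#' Time derivative of a scan set (dcdt mode)
#'
#' Pairwise difference of consecutive scans divided by the scan interval,
#' reported at the interval midpoints.  Raw scans are differenced by
#' default; optional pre-smoothing applies \code{savitzkyGolaySmooth} along
#' the radius first.
#'
#' @param scanSet a \code{ScanSet} with at least two scans
#' @param presmooth smooth each scan along the radius before differencing
#' @param window,order Savitzky-Golay parameters used when presmoothing
#' @return list with \code{midTimes} (s) and \code{dzdt} (matrix,
#'   signal/s, radii x midTimes)
#' @export
timeDerivative <- function(scanSet, presmooth = FALSE, window = 11,
                           order = 2) {
  z <- signalMatrix(scanSet)
  tt <- scanTimes(scanSet)
  if (length(tt) < 2) stop("need at least two scans for a time derivative")
  if (presmooth) z <- apply(z, 2, savitzkyGolaySmooth, window = window,
                            order = order)
  dt <- diff(tt)
  dz <- z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]
  list(midTimes = (tt[-1] + tt[-length(tt)]) / 2,
       dzdt = sweep(dz, 2, dt, `/`))
}

#' Smoothed derivatives of a scan set
#'
#' Convenience wrapper assembling the radial and time derivatives into a
#' \code{\linkS4class{DerivativeSet}}.
#'
#' @inheritParams radialDerivative
#' @export
derivativeSet <- function(scanSet, window = 11, order = 2) {
  dt <- timeDerivative(scanSet)
  new("DerivativeSet", radii = scanRadii(scanSet), times = scanTimes(scanSet),
      dzdr = radialDerivative(scanSet, window, order),
      midTimes = dt$midTimes, dzdt = dt$dzdt,
      window = window, order = order)
}
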