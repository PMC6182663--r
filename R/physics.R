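# Unit conventions throughout the package: radius cm, time s, angular
# velocity rad/s, sedimentation coefficient Svedberg at the interface
# (converted to seconds internally), masses Da, diffusion cm^2/s.

#' Rotor speed to angular velocity
#'
#' @param rpm rotor speed, revolutions per minute (> 0)
#' @return angular velocity, rad/s
#' @examples
#' rpmToOmega(40000)
#' @export
rpmToOmega <- function(rpm) {
  if (any(!is.finite(rpm)) || any(rpm <= 0)) stop("rpm must be positive")
  2 * pi * rpm / 60
}

#' Angular velocity to rotor speed
#' @param omega angular velocity, rad/s (> 0)
#' @return rotor speed, rev/min
#' @export
omegaToRpm <- function(omega) {
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be positive")
  omega * 60 / (2 * pi)
}

#' Diffusion coefficient from the Svedberg relation
#'
#' D = R T s / M^b, with s in seconds and M^b in kg/mol; returned in cm^2/s.
#' This ties the diffusional spreading of a boundary to the same two
#' molecular quantities that set its drift, so (s, M^b) fully determine a
#' component's transport.
#'
#' @param s sedimentation coefficient, Svedberg
#' @param buoyantMw buoyant molecular weight, Da
#' @param temperatureK absolute temperature, K
#' @return diffusion coefficient, cm^2/s
#' @examples
#' diffusionCoefficient(1.91, 4250, 293.15)  # lysozyme-like: ~1.1e-6 cm^2/s
#' @export
diffusionCoefficient <- function(s, buoyantMw, temperatureK) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("s must be positive")
  if (any(!is.finite(buoyantMw)) || any(buoyantMw <= 0))
    stop("buoyantMw must be positive")
  if (any(!is.finite(temperatureK)) || any(temperatureK <= 0))
    stop("temperatureK must be positive")
  # J mol^-1 K^-1 * K * s / (kg/mol) = m^2/s; 1e4 converts to cm^2/s
  .R_GAS * temperatureK * (s * .SVEDBERG) / (buoyantMw * 1e-3) * 1e4
}

#' Buoyant molecular weight
#'
#' M^b = M (1 - v-bar rho): the molar mass corrected for the buoyancy of the
#' displaced solvent.  Floating species (v-bar rho >= 1) are rejected; all
#' simulation machinery here assumes outward sedimentation.
#'
#' @param mw molecular weight, Da
#' @param vbar partial specific volume, cm^3/g
#' @param rho solvent density, g/cm^3
#' @return buoyant molecular weight, Da
#' @examples
#' buoyantMass(14300, 0.703, 0.9982)  # ~4264 Da
#' @export
buoyantMass <- function(mw, vbar, rho) {
  if (any(!is.finite(mw)) || any(mw <= 0)) stop("mw must be positive")
  if (any(vbar < 0) || any(rho < 0)) stop("vbar and rho must be non-negative")
  if (any(vbar * rho >= 1))
    stop("vbar * rho >= 1: species floats; flotation is not supported")
  mw * (1 - vbar * rho)
}

#' Signal fractions of a heterogeneous sample
#'
#' For components with specific signal constants q_k, loading mass
#' concentrations c0_k, molecular weights M_k and signal exponents
#' alpha_k (0 = mass-proportional detection, 1 = molar-proportional),
#' the fraction of the initially uniform signal contributed by component k
#' is y_k = (q_k c0_k / M_k^alpha_k) / sum_j (q_j c0_j / M_j^alpha_j).
#' With equal q and alpha = 0 these are the weight fractions; with equal q
#' and alpha = 1, the number fractions.
#'
#' @param q specific signal constants
#' @param c0 loading mass concentrations
#' @param mw molecular weights, Da
#' @param alpha signal exponents, each 0 or 1
#' @return numeric vector of signal fractions summing to 1
#' @export
signalFractions <- function(q, c0, mw, alpha = rep(0, length(q))) {
  n <- length(q)
  if (length(c0) != n || length(mw) != n || length(alpha) != n)
    stop("q, c0, mw and alpha must have equal length")
  if (any(q <= 0) || any(c0 <= 0) || any(mw <= 0))
    stop("q, c0 and mw must be positive")
  if (!all(alpha %in% c(0, 1))) stop("alpha must be 0 or 1")
  w <- q * c0 / mw^alpha
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) stop("degenerate sample: zero total signal")
  w / tot
}
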