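# Brownian-dynamics engine: centrifugal drift (exact exponential solution of
# dr/dt = s w^2 r over each step) plus Gaussian Brownian displacements of
# variance 2 D dt, with specular reflection at the meniscus and the cell
# bottom.  Trajectories are advanced by the compiled kernel (src/bd_kernel.cpp)
# on R's RNG stream, so everything is reproducible under set.seed().

#' Sample initial radial positions in a sector cell
#'
#' An initially uniform concentration in a sector-shaped cell corresponds to
#' a radial density proportional to r; this is sampled exactly by
#' r0 = sqrt(u (rb^2 - rm^2) + rm^2) with u uniform on (0, 1).  Draws come
#' from the current R RNG stream.
#'
#' @param n number of positions
#' @param geometry a \code{CellGeometry}
#' @param u optional uniform variates (for deterministic checks); length n
#' @return radial positions, cm
#' @export
sampleInitialPositions <- function(n, geometry, u = runif(n)) {
  stopifnot(n >= 1, length(u) == n)
  sqrt(u * (geometry@rb^2 - geometry@rm^2) + geometry@rm^2)
}

#' Sample radial positions from the sedimentation-equilibrium profile
#'
#' Inverse-CDF sampling of the sector-weighted Boltzmann profile
#' c(r) proportional to exp(sigma r^2 / 2), used to start simulations at
#' equilibrium (e.g. for fixed-point checks).
#'
#' @param n number of positions
#' @param geometry a \code{CellGeometry}
#' @param sigma reduced buoyant mass M^b omega^2 / (R T), cm^-2
#' @param u optional uniform variates
#' @return radial positions, cm
#' @export
sampleEquilibriumPositions <- function(n, geometry, sigma, u = runif(n)) {
  stopifnot(n >= 1, sigma > 0)
  em <- exp(sigma * geometry@rm^2 / 2)
  eb <- exp(sigma * geometry@rb^2 / 2)
  sqrt(2 * log(u * (eb - em) + em) / sigma)
}

#' Centrifugal drift displacement over one time step
#'
#' The exact integrated drift r [exp(s w^2 dt) - 1]: positive (outward) for
#' sedimenting species.
#'
#' @param r radial position, cm
#' @param s sedimentation coefficient, Svedberg
#' @param omega angular velocity, rad/s
#' @param dt time step, s
#' @return displacement, cm
#' @export
driftDisplacement <- function(r, s, omega, dt) {
  stopifnot(all(r > 0), all(dt >= 0))
  r * (exp((s * .SVEDBERG) * omega^2 * dt) - 1)
}

#' Brownian displacements over one time step
#'
#' Independent Gaussian draws with mean zero and variance 2 D dt, from the
#' current R RNG stream.
#'
#' @param n number of draws
#' @param D diffusion coefficient, cm^2/s
#' @param dt time step, s
#' @return displacements, cm
#' @export
brownianDisplacement <- function(n, D, dt) {
  stopifnot(D >= 0, dt >= 0)
  if (D == 0 || dt == 0) return(numeric(n))
  rnorm(n, mean = 0, sd = sqrt(2 * D * dt))
}

#' Reflect positions into the solution column
#'
#' Specular reflection about the violated bound, folded repeatedly until the
#' position lies inside [rm, rb].  Equivalent to the closed form
#' rm + fold((r - rm) mod 2L) with L = rb - rm.
#'
#' @param r positions, cm (finite)
#' @param geometry a \code{CellGeometry}
#' @return positions inside [rm, rb]
#' @export
applyBoundaries <- function(r, geometry) {
  if (any(!is.finite(r))) stop("non-finite particle position")
  L <- geometry@rb - geometry@rm
  d <- (r - geometry@rm) %% (2 * L)
  d <- ifelse(d > L, 2 * L - d, d)
  geometry@rm + d
}

#' Distribute particles among components
#'
#' The particle share of component k is phi_k = y_k^{2/3} / sum_j y_j^{2/3},
#' which equalises the contribution of each component's counting noise to
#' the total signal.  Counts are rounded with the largest component
#' absorbing the residual so they sum exactly to nPart.
#'
#' @param y signal fractions (positive, summing to 1)
#' @param nPart total particle count
#' @return integer counts per component, summing to nPart
#' @export
allocateParticles <- function(y, nPart) {
  if (abs(sum(y) - 1) > 1e-6 || any(y <= 0))
    stop("y must be positive and sum to 1")
  phi <- y^(2 / 3)
  phi <- phi / sum(phi)
  counts <- round(phi * nPart)
  counts[which.max(phi)] <- counts[which.max(phi)] + nPart - sum(counts)
  if (any(counts < 1))
    stop("nPart too small to give every component at least one particle")
  as.integer(counts)
}

#' Convert bin counts to a relative concentration profile
#'
#' Inverts the sector-cell binning: z/z0 at bin midpoint r_i is
#' (rb^2 - rm^2) / (2 chi r_i) * n(i, j) / nPart with chi the bin width, so
#' a density proportional to r (uniform loading) maps to 1 in every bin.
#'
#' @param counts integer matrix, nBins x nScans, column sums equal nPart
#' @param geometry a \code{CellGeometry}
#' @param nPart number of particles the counts refer to
#' @return matrix of z/z0 values on the bin midpoints
#' @export
countsToSignal <- function(counts, geometry, nPart) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) != nPart))
    stop("count conservation violated: column sums must equal nPart")
  nBins <- nrow(counts)
  chi <- (geometry@rb - geometry@rm) / nBins
  ri <- binMidpoints(geometry, nBins)
  pref <- (geometry@rb^2 - geometry@rm^2) / (2 * chi)
  sweep(counts / nPart, 1, pref / ri, `*`)
}

#' Radial bin midpoints
#' @param geometry a \code{CellGeometry}
#' @param nBins number of bins
#' @return r_i = rm + (i - 1/2) chi, cm
#' @export
binMidpoints <- function(geometry, nBins) {
  chi <- (geometry@rb - geometry@rm) / nBins
  geometry@rm + (seq_len(nBins) - 0.5) * chi
}

# Step grid: nSteps base intervals of tau = tRun/nSteps, truncated after the
# last scan, merged with the scan times, each interval optionally subdivided.
# Returns the grid (starting at 0) and the 1-based indices of the scan times.
makeStepGrid <- function(run, nSteps, substepsPerScan = 1) {
  st <- run@scanTimes
  tol <- max(run@tRun, 1) * 1e-9
  base <- seq(0, run@tRun, length.out = nSteps + 1)
  base <- base[base <= max(st) + tol]
  pts <- sort(c(base, st))
  pts <- pts[c(TRUE, diff(pts) > tol)]
  m <- as.integer(substepsPerScan)
  if (m > 1 && length(pts) > 1) {
    pieces <- lapply(seq_len(length(pts) - 1), function(i)
      seq(pts[i], pts[i + 1], length.out = m + 1)[-(m + 1)])
    pts <- c(unlist(pieces), pts[length(pts)])
  }
  record <- vapply(st, function(t) which.min(abs(pts - t)), 0L)
  if (any(abs(pts[record] - st) > tol))
    stop("internal error: scan time missing from step grid")
  list(stepTimes = pts, record = record)
}

#' Simulate one component's trajectories and bin occupancy
#'
#' Advances \code{nPart} particles of a single component through the run's
#' step grid (drift + Brownian + boundary reflection) and records the radial
#' bin occupancy at every scan time.  Draws come from the current R RNG
#' stream; seed management is the caller's job (see
#' \code{\link{simulateSample}}).
#'
#' @param component a \code{SoluteComponent}
#' @param geometry a \code{CellGeometry}
#' @param run a \code{RunConditions}
#' @param settings a \code{SimulationSettings} (nSteps, nBins,
#'   substepsPerScan; nPart unless overridden)
#' @param nPart particle count override (default \code{settings@nPart})
#' @param brownian set FALSE to disable the Brownian term (pure drift)
#' @param initialPositions optional starting radii (default: uniform
#'   loading via \code{\link{sampleInitialPositions}})
#' @return integer matrix nBins x nScans of occupancy counts; every column
#'   sums to nPart
#' @export
simulateComponent <- function(component, geometry, run, settings,
                              nPart = settings@nPart, brownian = TRUE,
                              initialPositions = NULL) {
  nPart <- as.integer(nPart)
  grid <- makeStepGrid(run, settings@nSteps, settings@substepsPerScan)
  if (is.null(initialPositions))
    initialPositions <- sampleInitialPositions(nPart, geometry)
  stopifnot(length(initialPositions) == nPart)
  D <- diffusionCoefficient(component@s, component@buoyantMw,
                            run@temperatureK)
  counts <- .bd_kernel(initialPositions,
                       component@s * .SVEDBERG, D,
                       rpmToOmega(run@rpm)^2,
                       grid$stepTimes, as.integer(grid$record),
                       geometry@rm, geometry@rb, as.integer(settings@nBins),
                       isTRUE(brownian))
  dimnames(counts) <- list(NULL, sprintf("scan%03d", seq_along(run@scanTimes)))
  counts
}

#' Simulate a multi-component scan set
#'
#' Allocates particles to components by the y^{2/3} rule, simulates each
#' component on its own deterministic child RNG stream derived from
#' \code{settings@seed}, and combines the occupancies into the signal
#' z(r_i, t_j) = z0 * (rb^2-rm^2)/(2 chi r_i) * sum_k y_k n_k(i,j)/N_k.
#' Identical inputs and seed give a bit-identical \code{ScanSet}.
#'
#' @param components list of \code{SoluteComponent}s whose signal fractions
#'   sum to 1
#' @param geometry a \code{CellGeometry}
#' @param run a \code{RunConditions}
#' @param settings a \code{SimulationSettings}
#' @param z0 loading signal (default 1)
#' @param brownian set FALSE to disable the Brownian term
#' @return a \code{ScanSet}
#' @examples
#' geom <- CellGeometry(6.0, 7.2)
#' run <- RunConditions(40000, 293.15, tRun = 3600,
#'                      scanTimes = c(0, 1800, 3600))
#' cmp <- list(SoluteComponent(s = 5, buoyantMw = 50000))
#' ss <- simulateSample(cmp, geom, run,
#'                      SimulationSettings(nPart = 1e4, nSteps = 10, seed = 7))
#' @export
simulateSample <- function(components, geometry, run, settings, z0 = 1,
                           brownian = TRUE) {
  if (!length(components)) stop("at least one component is required")
  y <- vapply(components, function(k) k@signalFraction, 0)
  if (abs(sum(y) - 1) > 1e-6) stop("signal fractions must sum to 1")
  y <- y / sum(y)
  alloc <- allocateParticles(y, settings@nPart)
  set.seed(settings@seed)
  childSeeds <- sample.int(.Machine$integer.max - 1, length(components))
  nBins <- as.integer(settings@nBins)
  z <- matrix(0, nBins, length(run@scanTimes))
  for (k in seq_along(components)) {
    set.seed(childSeeds[k])
    nk <- simulateComponent(components[[k]], geometry, run, settings,
                            nPart = alloc[k], brownian = brownian)
    z <- z + y[k] * countsToSignal(nk, geometry, alloc[k])
  }
  ScanSet(radii = binMidpoints(geometry, nBins), times = run@scanTimes,
          z = z0 * z, z0 = z0, geometry = geometry, run = run,
          metadata = list(settings = settings, seed = settings@seed,
                          components = components, brownian = brownian))
}

#' Interior mask for noise and misfit statistics
#'
#' The region adjacent to the cell bottom (default 0.2 cm) shows systematic
#' discretisation effects and is routinely excluded from data analysis; a
#' couple of meniscus bins are excluded likewise.
#'
#' @param radii radial bin midpoints, cm
#' @param geometry a \code{CellGeometry}
#' @param bottomMargin width of the excluded bottom region, cm
#' @param meniscusBins number of excluded bins at the meniscus
#' @return logical vector over the bins
#' @export
interiorMask <- function(radii, geometry, bottomMargin = 0.2,
                         meniscusBins = 2) {
  mask <- radii < geometry@rb - bottomMargin
  if (meniscusBins > 0) mask[seq_len(min(meniscusBins, length(mask)))] <- FALSE
  mask
}

#' Replicate-based noise estimate
#'
#' Repeats \code{simulateSample} with seeds \code{baseSeed},
#' \code{baseSeed + 1}, ... and returns the pointwise standard deviation of
#' z/z0 across replicates together with its mean over the interior bins
#' (all scans).
#'
#' @inheritParams simulateSample
#' @param nReplicates number of replicate simulations (>= 2)
#' @param baseSeed seed of the first replicate
#' @param bottomMargin,meniscusBins interior mask, see
#'   \code{\link{interiorMask}}
#' @return list with elements \code{sd} (matrix of per-point standard
#'   deviations of z/z0), \code{interiorMean}, \code{radii}, \code{times},
#'   \code{mask}
#' @export
estimateNoise <- function(components, geometry, run, settings,
                          nReplicates = 5, baseSeed = settings@seed,
                          bottomMargin = 0.2, meniscusBins = 2) {
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  reps <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    s <- settings
    s@seed <- baseSeed + i - 1
    ss <- simulateSample(components, geometry, run, s)
    reps[[i]] <- signalMatrix(ss) / loadingSignal(ss)
  }
  arr <- array(unlist(reps), dim = c(dim(reps[[1]]), nReplicates))
  mu <- apply(arr, c(1, 2), mean)
  sdmat <- sqrt(apply(sweep(arr, c(1, 2), mu)^2, c(1, 2), sum) /
                (nReplicates - 1))
  radii <- binMidpoints(geometry, as.integer(settings@nBins))
  mask <- interiorMask(radii, geometry, bottomMargin, meniscusBins)
  list(sd = sdmat, interiorMean = mean(sdmat[mask, ]), radii = radii,
       times = run@scanTimes, mask = mask)
}
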