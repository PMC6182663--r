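# Global nonlinear least-squares analysis: candidate models are re-simulated
# with the particle engine under common random numbers (fixed seed), so the
# stochastic objective is reproducible point-for-point and smooth enough for
# the Nelder-Mead simplex.

#' Square deviation between two scan sets
#'
#' The mean squared difference over the compared (r_i, t_j) points, divided
#' by the observed loading signal squared, so experiments with different
#' signal scales are comparable.  By default the bottom margin is excluded
#' from the comparison.
#'
#' @param calc calculated \code{ScanSet}
#' @param obs observed \code{ScanSet} on the identical grid
#' @param mask optional logical vector over the radial bins; default
#'   excludes \code{bottomMargin} cm at the bottom
#' @param bottomMargin excluded bottom region, cm (0 compares all bins)
#' @return the dimensionless square deviation
#' @export
delta2Single <- function(calc, obs, mask = NULL, bottomMargin = 0.2) {
  rc <- scanRadii(calc); ro <- scanRadii(obs)
  if (length(rc) != length(ro) || max(abs(rc - ro)) > 1e-8)
    stop("grid mismatch: calculated and observed radii differ")
  tc <- scanTimes(calc); to <- scanTimes(obs)
  if (length(tc) != length(to) || max(abs(tc - to)) > 1e-6 * max(to, 1))
    stop("grid mismatch: calculated and observed scan times differ")
  if (is.null(mask)) {
    geom <- scanGeometry(obs)
    mask <- if (!is.null(geom))
      interiorMask(ro, geom, bottomMargin, meniscusBins = 0)
    else rep(TRUE, length(ro))
  }
  z0 <- loadingSignal(obs)
  d <- (signalMatrix(calc)[mask, , drop = FALSE] -
        signalMatrix(obs)[mask, , drop = FALSE]) / z0
  mean(d^2)
}

# Simulate one experiment under a candidate model, on the observed grid.
simulateForExperiment <- function(experiment, components, nPart, seed) {
  ss <- experiment@scanSet
  settings <- SimulationSettings(nPart = nPart, nSteps = experiment@nSteps,
                                 nBins = length(scanRadii(ss)), seed = seed)
  simulateSample(components, scanGeometry(ss), scanRun(ss), settings,
                 z0 = loadingSignal(ss))
}

#' Global square deviation of a candidate model
#'
#' Simulates every experiment with the candidate components (fixed seed, so
#' repeated evaluation at the same parameters returns the identical value)
#' and returns the weight-averaged square deviation
#' sum_e W_e Delta_e^2 with the weights normalised to 1.
#'
#' @param experiments list of \code{SedExperiment}s
#' @param components candidate model: list of \code{SoluteComponent}s
#' @param nPart simulation fidelity of the evaluation
#' @param seed RNG seed held fixed across evaluations
#' @param bottomMargin excluded bottom region, cm
#' @return list with \code{delta2} (global) and \code{perExperiment}
#' @export
delta2Global <- function(experiments, components, nPart = 1e5, seed = 1,
                         bottomMargin = 0.2) {
  if (!length(experiments)) stop("at least one experiment is required")
  w <- vapply(experiments, function(e) e@weight, 0)
  if (sum(w) <= 0) stop("experiment weights must not all be zero")
  w <- w / sum(w)
  per <- vapply(seq_along(experiments), function(i) {
    calc <- simulateForExperiment(experiments[[i]], components, nPart, seed)
    delta2Single(calc, experiments[[i]]@scanSet, bottomMargin = bottomMargin)
  }, 0)
  list(delta2 = sum(w * per), perExperiment = per)
}

#' Nelder-Mead minimisation with trace
#'
#' Thin wrapper around \code{stats::optim(method = "Nelder-Mead")} that
#' records every objective evaluation.  Stops when the relative spread of
#' the simplex values falls below \code{reltol} or after \code{maxit}
#' iterations (the result is then flagged as not converged).
#'
#' @param objective function of a numeric parameter vector
#' @param initial starting parameter vector (objective must be finite there)
#' @param reltol relative convergence tolerance
#' @param maxit maximum iterations
#' @return list with \code{par}, \code{value}, \code{evaluations},
#'   \code{converged}, \code{history}
#' @export
simplexMinimize <- function(objective, initial, reltol = 1e-6, maxit = 2000) {
  env <- new.env()
  env$history <- numeric()
  wrapped <- function(p) {
    v <- objective(p)
    if (!is.finite(v)) v <- .Machine$double.xmax / 2
    env$history <- c(env$history, v)
    v
  }
  v0 <- objective(initial)
  if (!is.finite(v0)) stop("objective is not finite at the initial point")
  res <- optim(initial, wrapped, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  list(par = res$par, value = res$value,
       evaluations = unname(res$counts[1]),
       converged = res$convergence == 0, history = env$history)
}

# (s, M^b, y) trios <-> unconstrained parameter vector:
# log s, log M^b per component plus nc-1 softmax logits for y (last logit 0).
packParams <- function(components) {
  s <- vapply(components, function(k) k@s, 0)
  mb <- vapply(components, function(k) k@buoyantMw, 0)
  y <- vapply(components, function(k) k@signalFraction, 0)
  nc <- length(components)
  th <- c(log(s), log(mb))
  if (nc > 1) th <- c(th, log(y[-nc] / y[nc]))
  th
}

unpackParams <- function(theta, nc) {
  s <- exp(theta[seq_len(nc)])
  mb <- exp(theta[nc + seq_len(nc)])
  a <- if (nc > 1) c(theta[2 * nc + seq_len(nc - 1)], 0) else 0
  ey <- exp(a - max(a))
  y <- ey / sum(ey)
  lapply(seq_len(nc), function(k)
    SoluteComponent(s = s[k], buoyantMw = mb[k], signalFraction = y[k]))
}

# One coordinate-descent sweep: per parameter, a three-point parabola at
# +/- h in log space, stepping to the parabola minimum (clamped to 2h) when
# it improves the objective.  Used to debias the weakly determined
# parameters against the common-random-number noise of the cheaper search.
polishSweep <- function(theta, objective, h, idx = seq_along(theta)) {
  f0 <- objective(theta)
  evals <- 1L
  for (i in idx) {
    tp <- theta; tp[i] <- theta[i] + h; fp <- objective(tp)
    tm <- theta; tm[i] <- theta[i] - h; fm <- objective(tm)
    evals <- evals + 2L
    curv <- fp - 2 * f0 + fm
    if (is.finite(curv) && curv > 0) {
      step <- max(min(0.5 * h * (fm - fp) / curv, 2 * h), -2 * h)
      cand <- theta; cand[i] <- theta[i] + step
      fc <- objective(cand)
      evals <- evals + 1L
      if (fc < f0) { theta <- cand; f0 <- fc }
    } else if (fp < f0) { theta <- tp; f0 <- fp
    } else if (fm < f0) { theta <- tm; f0 <- fm }
  }
  list(theta = theta, value = f0, evals = evals)
}

#' Fit a fixed number of components to one or more experiments
#'
#' Minimises the global square deviation over the 3 nc - 1 free parameters
#' (log s_k, log M^b_k, and nc - 1 softmax-transformed signal fractions;
#' one y is fixed by their unit sum).  The search runs Nelder-Mead at
#' fidelity \code{nPart} under a fixed seed, restarting the simplex from
#' the optimum until the objective stops improving (the simplex otherwise
#' tends to collapse early on this surface).  An optional multi-fidelity
#' polish then refines each parameter by coordinate-wise parabolic steps at
#' increasing particle numbers, removing the parameter bias induced by the
#' finite search fidelity.  The reported square deviations are re-evaluated
#' once at \code{nPartFinal} (with a fresh seed), so they reflect the
#' data's noise rather than the search simulations'.
#'
#' @param experiments list of \code{SedExperiment}s
#' @param initialComponents starting model (defines the component count)
#' @param nPart search simulation fidelity (particles)
#' @param nPartFinal fidelity of the final reported evaluation; 0 skips the
#'   re-evaluation and reports the search-fidelity objective instead
#' @param seed RNG seed for the common-random-number objective
#' @param reltol,maxit simplex controls, see \code{\link{simplexMinimize}}
#' @param bottomMargin excluded bottom region, cm
#' @param nRestarts maximal number of simplex restarts
#' @param restartTol relative improvement below which restarting stops
#' @param search run the simplex search (FALSE polishes/evaluates the
#'   initial model as is)
#' @param polish apply the multi-fidelity coordinate polish
#' @param polishMultipliers per-sweep fidelity, as multiples of \code{nPart}
#' @param polishSteps per-sweep coordinate step h in log space
#' @param mbSweeps extra buoyant-mass-only sweeps after the full sweeps
#' @param mbSweepMultiplier,mbSweepStep fidelity multiple and step of the
#'   extra buoyant-mass sweeps
#' @return a \code{SedFitResult}
#' @export
fitNComponents <- function(experiments, initialComponents, nPart = 1e5,
                           nPartFinal = 1e7, seed = 1, reltol = 1e-6,
                           maxit = 2000, bottomMargin = 0.2, nRestarts = 3,
                           restartTol = 0.005, search = TRUE, polish = TRUE,
                           polishMultipliers = c(10, 10, 30),
                           polishSteps = c(0.12, 0.06, 0.04),
                           mbSweeps = 2, mbSweepMultiplier = 30,
                           mbSweepStep = 0.03) {
  nc <- length(initialComponents)
  objFor <- function(np) function(theta) {
    comps <- tryCatch(unpackParams(theta, nc), error = function(e) NULL)
    if (is.null(comps)) return(Inf)
    delta2Global(experiments, comps, nPart = np, seed = seed,
                 bottomMargin = bottomMargin)$delta2
  }
  objective <- objFor(nPart)
  theta <- packParams(initialComponents)
  history <- numeric(); evals <- 0L; converged <- TRUE
  value <- Inf
  if (search) for (r in seq_len(nRestarts + 1)) {
    res <- simplexMinimize(objective, theta, reltol = reltol, maxit = maxit)
    theta <- res$par
    evals <- evals + res$evaluations
    history <- c(history, res$history)
    converged <- res$converged
    improvement <- (value - res$value) / max(res$value, .Machine$double.eps)
    value <- res$value
    if (improvement < restartTol) break
  }
  if (polish) {
    for (i in seq_along(polishMultipliers)) {
      sw <- polishSweep(theta, objFor(polishMultipliers[i] * nPart),
                        polishSteps[i])
      theta <- sw$theta
      evals <- evals + sw$evals
      history <- c(history, sw$value)
    }
    # the buoyant masses are the softest directions (their diffusional
    # signature is weak); give them extra high-fidelity sweeps
    mbIdx <- nc + seq_len(nc)
    for (k in seq_len(mbSweeps)) {
      sw <- polishSweep(theta, objFor(mbSweepMultiplier * nPart),
                        mbSweepStep, idx = mbIdx)
      moved <- max(abs(sw$theta - theta))
      theta <- sw$theta
      evals <- evals + sw$evals
      history <- c(history, sw$value)
      if (moved < 0.005) break
    }
  }
  comps <- unpackParams(theta, nc)
  if (nPartFinal > 0) {
    final <- delta2Global(experiments, comps, nPart = nPartFinal,
                          seed = seed + 1, bottomMargin = bottomMargin)
  } else {
    final <- delta2Global(experiments, comps, nPart = nPart, seed = seed,
                          bottomMargin = bottomMargin)
  }
  new("SedFitResult", components = comps, delta2 = final$delta2,
      delta2PerExperiment = final$perExperiment,
      nIterations = evals, converged = converged,
      history = history)
}

# Data-driven single-component starting guess: s from the boundary track of
# the fastest experiment, M^b from the Svedberg relation with a
# boundary-spread-derived D; falls back to a mid-range guess.
guessInitialComponent <- function(experiments, fallbackS = 5,
                                  fallbackMb = 50000) {
  rpms <- vapply(experiments, function(e) scanRun(e@scanSet)@rpm, 0)
  e <- experiments[[which.max(rpms)]]
  ss <- e@scanSet
  run <- scanRun(ss)
  omega <- rpmToOmega(run@rpm)
  s <- tryCatch({
    tr <- estimateSFromBoundary(locateBoundary(ss), omega)
    if (is.finite(tr@estimatedS) && tr@estimatedS > 0) tr@estimatedS
    else fallbackS
  }, error = function(e) fallbackS)
  mb <- tryCatch({
    D <- boundarySpreadD(ss)
    if (is.finite(D) && D > 0)
      .R_GAS * run@temperatureK * (s * .SVEDBERG) / (D * 1e-4) * 1e3
    else fallbackMb
  }, error = function(e) fallbackMb)
  if (!is.finite(mb) || mb <= 0) mb <- fallbackMb
  SoluteComponent(s = s, buoyantMw = mb, signalFraction = 1)
}

# Apparent diffusion coefficient from the growth of the boundary width:
# the 25-75% crossing width, converted to a Gaussian sd, obeys sd^2 = 2 D t.
boundarySpreadD <- function(scanSet, bottomMargin = 0.2) {
  z <- signalMatrix(scanSet) / loadingSignal(scanSet)
  radii <- scanRadii(scanSet)
  tt <- scanTimes(scanSet)
  geom <- scanGeometry(scanSet)
  upper <- geom@rb - bottomMargin
  win <- which(radii >= radii[1] + 0.75 * (upper - radii[1]) &
               radii <= upper)
  crossing <- function(zz, h) {
    below <- which(zz < h)
    below <- below[below < min(win)]
    if (!length(below)) return(NA_real_)
    i <- max(below)
    if (i >= length(zz)) return(NA_real_)
    radii[i] + (h - zz[i]) / (zz[i + 1] - zz[i]) * (radii[i + 1] - radii[i])
  }
  sd2 <- vapply(seq_along(tt), function(j) {
    pl <- median(z[win, j])
    if (pl <= 0.05) return(NA_real_)
    r25 <- crossing(z[, j], 0.25 * pl)
    r75 <- crossing(z[, j], 0.75 * pl)
    if (is.na(r25) || is.na(r75) || r75 <= r25) return(NA_real_)
    ((r75 - r25) / 1.349)^2
  }, 0)
  ok <- is.finite(sd2) & tt > 0
  if (sum(ok) < 2) return(NA_real_)
  fit <- lm(sd2[ok] ~ tt[ok])
  coef(fit)[[2]] / 2
}

#' Automatic fit with heuristic model expansion
#'
#' Starts from a single component (initial guess derived from the data
#' unless supplied), then repeatedly expands the model: the component with
#' the largest signal fraction is split into two children at half and twice
#' its fitted (s, M^b), sharing its y equally -- for one component this is
#' exactly the half/twice rule with y = 0.5/0.5.  Expansion stops when the
#' square deviation improves by less than \code{improvementFactor}, or at
#' \code{maxComponents}; the best accepted model is returned.
#'
#' @inheritParams fitNComponents
#' @param maxComponents largest model size to consider
#' @param improvementFactor required factor of improvement in the square
#'   deviation for an expansion to be accepted (default 2)
#' @param initialModel optional list of \code{SoluteComponent}s overriding
#'   the data-derived single-component start
#' @param verbose print progress
#' @return a \code{SedFitResult} for the accepted model
#' @export
fitAuto <- function(experiments, maxComponents = 2, nPart = 1e5,
                    nPartFinal = 1e7, seed = 1, reltol = 1e-6, maxit = 2000,
                    bottomMargin = 0.2, improvementFactor = 2,
                    initialModel = NULL, polish = TRUE, verbose = FALSE) {
  stopifnot(maxComponents >= 1)
  init <- if (is.null(initialModel)) list(guessInitialComponent(experiments))
          else initialModel
  # model selection at search fidelity (comparable common-random-number
  # objectives); the accepted model is refined and re-evaluated at the end
  best <- fitNComponents(experiments, init, nPart = nPart, nPartFinal = 0,
                         seed = seed, reltol = reltol, maxit = maxit,
                         bottomMargin = bottomMargin, polish = FALSE)
  if (verbose)
    message(sprintf("n_c = %d: search Delta^2 = %.4g (%d evaluations)",
                    length(init), best@delta2, best@nIterations))
  while (length(best@components) < maxComponents) {
    expanded <- expandModel(best@components)
    cand <- fitNComponents(experiments, expanded, nPart = nPart,
                           nPartFinal = 0, seed = seed, reltol = reltol,
                           maxit = maxit, bottomMargin = bottomMargin,
                           polish = FALSE)
    if (verbose)
      message(sprintf("n_c = %d: search Delta^2 = %.4g (%d evaluations)",
                      length(expanded), cand@delta2, cand@nIterations))
    if (best@delta2 / cand@delta2 < improvementFactor) break
    best <- cand
  }
  refined <- fitNComponents(experiments, best@components, nPart = nPart,
                            nPartFinal = nPartFinal, seed = seed,
                            reltol = reltol, maxit = maxit,
                            bottomMargin = bottomMargin, search = FALSE,
                            polish = polish)
  refined@nIterations <- refined@nIterations + best@nIterations
  refined@converged <- best@converged
  if (verbose)
    message(sprintf("refined n_c = %d: Delta^2 = %.4g",
                    length(refined@components), refined@delta2))
  refined
}

# Split the largest-fraction component into (s/2, M^b/2) and (2s, 2M^b)
# children sharing its signal fraction equally.
expandModel <- function(components) {
  y <- vapply(components, function(k) k@signalFraction, 0)
  i <- which.max(y)
  k <- components[[i]]
  children <- list(
    SoluteComponent(s = k@s / 2, buoyantMw = k@buoyantMw / 2,
                    signalFraction = y[i] / 2),
    SoluteComponent(s = k@s * 2, buoyantMw = k@buoyantMw * 2,
                    signalFraction = y[i] / 2))
  c(components[-i], children)
}
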