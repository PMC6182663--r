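geom <- testGeometry()

makeObsPair <- function() {
  run <- svRun(nScans = 4, tRun = 7200)
  radii <- binMidpoints(geom, 50)
  z <- matrix(runif(200, 0.5, 1), 50, 4)
  obs <- ScanSet(radii, run@scanTimes, z, z0 = 2, geometry = geom, run = run)
  list(obs = obs, run = run, radii = radii, z = z)
}

test_that("the square deviation is a z0-normalised mean square", {
  set.seed(8)
  p <- makeObsPair()
  expect_equal(delta2Single(p$obs, p$obs), 0)
  shifted <- ScanSet(p$radii, p$run@scanTimes, p$z + 0.3, z0 = 2,
                     geometry = geom, run = p$run)
  expect_equal(delta2Single(shifted, p$obs), (0.3 / 2)^2, tolerance = 1e-12)
  # Gaussian perturbation: expectation sigma^2 / z0^2
  noisy <- ScanSet(p$radii, p$run@scanTimes,
                   p$z + rnorm(200, sd = 0.05), z0 = 2,
                   geometry = geom, run = p$run)
  expect_equal(delta2Single(noisy, p$obs, bottomMargin = 0),
               0.05^2 / 4, tolerance = 0.25)
  other <- ScanSet(p$radii + 0.001, p$run@scanTimes, p$z, z0 = 2,
                   geometry = geom, run = p$run)
  expect_error(delta2Single(other, p$obs), "grid mismatch")
})

test_that("the global objective is deterministic and self-consistent", {
  run <- svRun(nScans = 4, tRun = 7200)
  comps <- list(lysLike(0.6), fibLike(0.4))
  setts <- SimulationSettings(nPart = 2e4, nSteps = 10, nBins = 40, seed = 77)
  obs <- simulateSample(comps, geom, run, setts)
  e <- SedExperiment(obs, weight = 1, nSteps = 10)
  # same model, same seed, same fidelity: the simulation is reproduced
  d <- delta2Global(list(e), comps, nPart = 2e4, seed = 77)
  expect_equal(d$delta2, 0)
  # repeated evaluation returns the identical value
  d1 <- delta2Global(list(e), comps, nPart = 1e4, seed = 3)$delta2
  d2 <- delta2Global(list(e), comps, nPart = 1e4, seed = 3)$delta2
  expect_identical(d1, d2)
  # equal weights average the per-experiment deviations
  e2 <- SedExperiment(obs, weight = 1, nSteps = 10)
  g <- delta2Global(list(e, e2), comps, nPart = 1e4, seed = 3)
  expect_equal(g$delta2, mean(g$perExperiment))
})

test_that("the simplex wrapper minimises standard test functions", {
  bowl <- function(p) (p[1] - 2)^2 + 3 * (p[2] + 1)^2
  res <- simplexMinimize(bowl, c(5, 5), reltol = 1e-10)
  expect_equal(res$par, c(2, -1), tolerance = 1e-3)
  expect_true(res$converged)
  expect_equal(length(res$history), res$evaluations)
  rosen <- function(p) 100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2
  res <- simplexMinimize(rosen, c(-1.2, 1), reltol = 1e-12, maxit = 5000)
  expect_equal(res$par, c(1, 1), tolerance = 1e-4)
  # a parameter the objective ignores cannot stop the minimisation
  flat <- function(p) (p[1] - 1)^2
  res <- simplexMinimize(flat, c(4, 0.3), reltol = 1e-10)
  expect_equal(res$par[1], 1, tolerance = 1e-3)
  expect_true(is.finite(res$par[2]))
  expect_error(simplexMinimize(function(p) NaN, 1), "not finite")
})

test_that("parameter packing round trips component trios", {
  set.seed(23)
  for (nc in 1:3) {
    y <- runif(nc); y <- y / sum(y)
    comps <- lapply(seq_len(nc), function(k)
      SoluteComponent(runif(1, 0.5, 20), runif(1, 1e3, 1e5), y[k]))
    back <- sedbd:::unpackParams(sedbd:::packParams(comps), nc)
    expect_equal(vapply(back, function(k) k@s, 0),
                 vapply(comps, function(k) k@s, 0), tolerance = 1e-12)
    expect_equal(vapply(back, function(k) k@signalFraction, 0), y,
                 tolerance = 1e-12)
  }
})

test_that("a single-component fit recovers the generating parameters", {
  run <- svRun(nScans = 7)
  truth <- SoluteComponent(3.5, 30000, 1)
  obs <- simulateSample(list(truth), geom, run,
                        SimulationSettings(4e6, 20, 100, seed = 55))
  obs <- addMeasurementNoise(obs, sigma = 0.02, seed = 9)
  e <- SedExperiment(obs, weight = 1, nSteps = 20)
  fit <- fitNComponents(list(e), list(SoluteComponent(6, 80000, 1)),
                        nPart = 5e4, nPartFinal = 4e6, seed = 2,
                        polishMultipliers = c(5, 20),
                        polishSteps = c(0.08, 0.05))
  k <- fitComponents(fit)[[1]]
  expect_equal(k@s, 3.5, tolerance = 0.02)
  expect_equal(k@buoyantMw, 30000, tolerance = 0.10)
  # final deviation sits at the injected noise floor (sigma/z0)^2
  expect_gt(fitDelta2(fit), 0.5 * 0.02^2)
  expect_lt(fitDelta2(fit), 2.5 * 0.02^2)
})

test_that("model expansion stops when a second component does not help", {
  run <- svRun(nScans = 6, tRun = 14400)
  truth <- SoluteComponent(3.5, 30000, 1)
  obs <- simulateSample(list(truth), geom, run,
                        SimulationSettings(5e5, 20, 60, seed = 66))
  e <- SedExperiment(obs, weight = 1, nSteps = 20)
  fit <- fitAuto(list(e), maxComponents = 2, nPart = 3e4, nPartFinal = 5e5,
                 seed = 4, maxit = 600)
  expect_length(fitComponents(fit), 1)
  expect_equal(fitComponents(fit)[[1]]@s, 3.5, tolerance = 0.05)
})

test_that("expansion is disabled when only one component is allowed", {
  run <- svRun(nScans = 4, tRun = 7200)
  obs <- simulateSample(list(lysLike(1)), geom, run,
                        SimulationSettings(2e4, 10, 40, seed = 5))
  e <- SedExperiment(obs, weight = 1, nSteps = 10)
  fit <- fitAuto(list(e), maxComponents = 1, nPart = 1e4, nPartFinal = 0,
                 seed = 3, maxit = 300, polish = FALSE,
                 initialModel = list(SoluteComponent(2, 5000, 1)))
  expect_length(fitComponents(fit), 1)
})

test_that("the half/twice expansion rule splits the dominant component", {
  comps <- list(SoluteComponent(3, 4000, 1))
  ex <- sedbd:::expandModel(comps)
  expect_length(ex, 2)
  expect_equal(vapply(ex, function(k) k@s, 0), c(1.5, 6))
  expect_equal(vapply(ex, function(k) k@buoyantMw, 0), c(2000, 8000))
  expect_equal(vapply(ex, function(k) k@signalFraction, 0), c(0.5, 0.5))
  three <- sedbd:::expandModel(list(SoluteComponent(2, 3000, 0.7),
                                    SoluteComponent(8, 90000, 0.3)))
  expect_length(three, 3)
  expect_equal(sum(vapply(three, function(k) k@signalFraction, 0)), 1)
})
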