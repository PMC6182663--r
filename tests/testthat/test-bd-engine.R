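geom <- testGeometry()

test_that("initial positions sample density proportional to r", {
  expect_equal(sampleInitialPositions(2, geom, u = c(0, 1)),
               c(geom@rm, geom@rb))
  set.seed(7)
  r0 <- sampleInitialPositions(1e5, geom)
  edges <- seq(geom@rm, geom@rb, length.out = 21)
  obs <- table(cut(r0, edges))
  expected <- diff(edges^2) / (geom@rb^2 - geom@rm^2) * 1e5
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 19))
})

test_that("drift displacement is the integrated outward drift", {
  expect_equal(driftDisplacement(6.5, 1.91, rpmToOmega(40000), 0), 0)
  expect_equal(driftDisplacement(6.5, 1e-300, rpmToOmega(40000), 100), 0,
               tolerance = 1e-15)
  d <- driftDisplacement(6.0, 1.91, rpmToOmega(40000), 480)
  expect_equal(d, 6.0 * (exp(1.91e-13 * rpmToOmega(40000)^2 * 480) - 1),
               tolerance = 1e-12)
  expect_equal(d, 9.66e-3, tolerance = 1e-3)
  expect_true(all(driftDisplacement(c(6, 6.5, 7), 5, 4000, 60) > 0))
})

test_that("Brownian displacements have mean zero and variance 2 D dt", {
  expect_identical(brownianDisplacement(5, 0, 100), numeric(5))
  expect_identical(brownianDisplacement(5, 1e-6, 0), numeric(5))
  D <- 1.1e-6; dt <- 1440
  set.seed(11)
  x <- brownianDisplacement(1e6, D, dt)
  expect_lt(abs(mean(x)), 4 * sqrt(2 * D * dt / 1e6))
  expect_equal(var(x), 2 * D * dt, tolerance = 0.01)
})

test_that("boundary reflection folds every finite position into the cell", {
  expect_equal(applyBoundaries(c(6.3, 7.0), geom), c(6.3, 7.0))
  expect_equal(applyBoundaries(geom@rb + 0.1, geom), geom@rb - 0.1)
  expect_equal(applyBoundaries(geom@rm - 0.25, geom), geom@rm + 0.25)
  set.seed(3)
  r <- runif(2000, -50, 50)
  folded <- applyBoundaries(r, geom)
  expect_true(all(folded >= geom@rm & folded <= geom@rb))
  # repeated single reflections agree with the closed-form fold
  foldOnce <- function(x) {
    while (x < geom@rm || x > geom@rb)
      x <- if (x < geom@rm) 2 * geom@rm - x else 2 * geom@rb - x
    x
  }
  expect_equal(folded[1:50], vapply(r[1:50], foldOnce, 0), tolerance = 1e-9)
  expect_error(applyBoundaries(c(1, NA), geom), "finite")
  expect_error(applyBoundaries(Inf, geom), "finite")
})

test_that("particle allocation follows the y^(2/3) rule and conserves nPart", {
  expect_identical(allocateParticles(1, 1000), 1000L)
  expect_identical(allocateParticles(c(0.5, 0.5), 1000), c(500L, 500L))
  phi1 <- 0.6^(2 / 3) / (0.6^(2 / 3) + 0.4^(2 / 3))
  cnt <- allocateParticles(c(0.6, 0.4), 1e6)
  expect_lte(abs(cnt[1] - round(phi1 * 1e6)), 1)
  expect_identical(sum(cnt), 1000000L)
  set.seed(5)
  for (i in 1:10) {
    y <- runif(sample(2:5, 1)); y <- y / sum(y)
    cnt <- allocateParticles(y, 12345)
    expect_identical(sum(cnt), 12345L)
    expect_true(all(cnt >= 1))
  }
  expect_error(allocateParticles(c(0.999, 0.001), 10), "at least one")
})

test_that("counts-to-signal normalisation inverts the sector binning", {
  nBins <- 10
  ri <- binMidpoints(geom, nBins)
  chi <- (geom@rb - geom@rm) / nBins
  # all particles in one bin
  counts <- matrix(0L, nBins, 1); counts[4, 1] <- 500L
  z <- countsToSignal(counts, geom, 500)
  expect_equal(z[4, 1], (geom@rb^2 - geom@rm^2) / (2 * chi * ri[4]))
  expect_equal(z[-4, 1], rep(0, nBins - 1))
  # doubling nPart at fixed proportions leaves the signal unchanged
  z2 <- countsToSignal(2L * counts, geom, 1000)
  expect_equal(z2, z)
  expect_error(countsToSignal(counts, geom, 400), "conservation")
})

test_that("zero-duration runs return the binned initial distribution", {
  run0 <- RunConditions(40000, 293.15, tRun = 0, scanTimes = 0)
  set.seed(21)
  pos <- sampleInitialPositions(5000, geom)
  cnt <- simulateComponent(lysLike(), geom, run0,
                           SimulationSettings(5000, 1, 20),
                           nPart = 5000, initialPositions = pos)
  manual <- table(cut(pos, seq(geom@rm, geom@rb, length.out = 21)))
  expect_equal(as.numeric(cnt[, 1]), as.numeric(manual))
})

test_that("particle count is conserved at every scan", {
  run <- svRun(nScans = 6)
  set.seed(2)
  for (cmp in list(lysLike(), fibLike())) {
    cnt <- simulateComponent(cmp, geom, run, SimulationSettings(2e4, 20, 50),
                             nPart = 2e4)
    expect_identical(as.integer(colSums(cnt)), rep(20000L, 6))
  }
})

test_that("scan sets are bit-for-bit reproducible under a fixed seed", {
  run <- svRun(nScans = 5)
  setts <- SimulationSettings(nPart = 3e4, nSteps = 20, nBins = 50, seed = 42)
  comps <- list(lysLike(0.6), fibLike(0.4))
  a <- simulateSample(comps, geom, run, setts)
  b <- simulateSample(comps, geom, run, setts)
  expect_identical(signalMatrix(a), signalMatrix(b))
  setts@seed <- 43
  c <- simulateSample(comps, geom, run, setts)
  expect_false(identical(signalMatrix(a), signalMatrix(c)))
})

test_that("the loading scan has unit mean signal within sampling error", {
  run <- svRun(nScans = 3)
  setts <- SimulationSettings(nPart = 1e5, nSteps = 10, nBins = 50, seed = 9)
  ss <- simulateSample(list(lysLike(0.6), fibLike(0.4)), geom, run, setts)
  z <- signalMatrix(ss)[, 1]
  # binomial sampling error of the interior mean of z/z0
  se <- sqrt(50 / 1e5)
  expect_lt(abs(mean(z[3:45]) - 1), 3 * se)
})

test_that("a single component reduces to its own rescaled occupancy", {
  run <- svRun(nScans = 4)
  setts <- SimulationSettings(nPart = 2e4, nSteps = 10, nBins = 40, seed = 17)
  ss <- simulateSample(list(lysLike(1)), geom, run, setts)
  set.seed(setts@seed)
  childSeed <- sample.int(.Machine$integer.max - 1, 1)
  set.seed(childSeed)
  cnt <- simulateComponent(lysLike(1), geom, run, setts, nPart = 2e4)
  expect_equal(unname(signalMatrix(ss)),
               unname(countsToSignal(cnt, geom, 2e4)))
})

test_that("without diffusion the boundary obeys the exponential drift law", {
  run <- svRun(nScans = 6)
  setts <- SimulationSettings(nPart = 1e5, nSteps = 20, nBins = 100, seed = 4)
  ss <- simulateSample(list(lysLike(1)), geom, run, setts, brownian = FALSE)
  omega <- rpmToOmega(run@rpm)
  chi <- (geom@rb - geom@rm) / 100
  track <- locateBoundary(ss)
  for (j in 2:6) {
    rOracle <- geom@rm * exp(1.91e-13 * omega^2 * run@scanTimes[j])
    expect_lt(abs(track@boundaryRadii[j] - rOracle), chi)
  }
})

test_that("interior profiles are insensitive to the number of time steps", {
  run <- svRun(nScans = 6)
  comps <- list(lysLike(0.6), fibLike(0.4))
  mk <- function(ns, seed) signalMatrix(simulateSample(
    comps, geom, run, SimulationSettings(1e5, ns, 50, seed = seed)))
  z50 <- mk(50, 1)
  z200 <- mk(200, 2)
  noise <- estimateNoise(comps, geom, run,
                         SimulationSettings(1e5, 50, 50, seed = 10),
                         nReplicates = 4)
  diffs <- abs(z50 - z200)[noise$mask, ]
  # pointwise differences behave like independent replicates, not bias
  expect_lt(mean(diffs), 3 * mean(noise$sd[noise$mask, ]))
})

test_that("replicate noise shrinks when particles are added or bins widened", {
  run <- svRun(nScans = 4)
  comps <- list(lysLike(0.6), fibLike(0.4))
  noiseAt <- function(nPart, nBins = 50)
    estimateNoise(comps, geom, run,
                  SimulationSettings(nPart, 10, nBins, seed = 30),
                  nReplicates = 6)$interiorMean
  n1 <- noiseAt(1e4)
  n4 <- noiseAt(4e4)
  expect_equal(n4 / n1, 0.5, tolerance = 0.2)     # 1/sqrt(N) scaling
  expect_lt(noiseAt(4e4, nBins = 25), noiseAt(4e4, nBins = 50))
  expect_error(estimateNoise(comps, geom, run,
                             SimulationSettings(1e3, 5, 20, seed = 1),
                             nReplicates = 1), "nReplicates")
})

test_that("a sample started from equilibrium stays at equilibrium", {
  cmp <- lysLike(1)
  omega <- rpmToOmega(10000)
  sigma <- equilibriumSigma(cmp@buoyantMw, omega, 293.15)
  run <- RunConditions(10000, 293.15, tRun = 72000,
                       scanTimes = c(0, 72000))
  set.seed(88)
  pos <- sampleEquilibriumPositions(1e5, geom, sigma)
  cnt <- simulateComponent(cmp, geom, run,
                           SimulationSettings(1e5, 200, 40, seed = 1),
                           nPart = 1e5, initialPositions = pos)
  ef <- equilibriumBinFractions(cmp, geom, omega, 293.15, 40) * 1e5
  mask <- interiorMask(binMidpoints(geom, 40), geom)
  chi2 <- sum((cnt[mask, 2] - ef[mask])^2 / ef[mask])
  expect_lt(chi2, qchisq(0.999, sum(mask) - 1))
})
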