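geom <- testGeometry()
omega40 <- rpmToOmega(40000)

test_that("no-diffusion profile is a step with radial-dilution plateau", {
  cmp <- lysLike()
  p0 <- noDiffusionProfile(cmp, geom, omega40, 0)
  expect_equal(p0$boundary, geom@rm)
  expect_equal(p0$z, rep(1, length(p0$z)))
  t <- 10800
  p <- noDiffusionProfile(cmp, geom, omega40, t)
  a <- 1.91e-13 * omega40^2 * t
  expect_equal(p$boundary, geom@rm * exp(a), tolerance = 1e-12)
  # plateau equals both exp(-2 s w^2 t) and the square-dilution form
  expect_equal(p$plateau, exp(-2 * a), tolerance = 1e-12)
  expect_equal(p$plateau, (geom@rm / p$boundary)^2, tolerance = 1e-12)
  expect_equal(unique(p$z[p$radii >= p$boundary]), p$plateau)
  expect_equal(unique(p$z[p$radii < p$boundary]), 0)
})

test_that("no-diffusion profile conserves sector-weighted mass", {
  cmp <- lysLike()
  for (t in c(4800, 9600, 19200)) {
    p <- noDiffusionProfile(cmp, geom, omega40, t)
    a <- 1.91e-13 * omega40^2 * t
    # untruncated: material occupies [boundary, rb e^{a}]
    outer <- geom@rb * exp(a)
    mass <- p$plateau * (outer^2 - p$boundary^2) / 2
    expect_equal(mass, (geom@rb^2 - geom@rm^2) / 2, tolerance = 1e-10)
  }
})

test_that("equilibrium profile reduces to uniform loading at low speed", {
  cmp <- lysLike()
  eq0 <- equilibriumProfile(cmp, geom, omega = 1e-9, temperatureK = 293.15)
  expect_equal(eq0$z, rep(1, 200))
  eq <- equilibriumProfile(cmp, geom, rpmToOmega(10000), 293.15)
  expect_equal(eq$sigma, 0.1912, tolerance = 1e-3)
  expect_equal(eq$sigma,
               4.25 * rpmToOmega(10000)^2 / (8.314 * 293.15) * 1e-4,
               tolerance = 1e-12)
  # sector-weighted integral equals that of the uniform profile
  r <- seq(geom@rm, geom@rb, length.out = 20001)
  z <- equilibriumProfile(cmp, geom, rpmToOmega(10000), 293.15, radii = r)$z
  trapz <- sum((z[-1] * r[-1] + z[-length(r)] * r[-length(r)]) / 2 * diff(r))
  expect_equal(trapz, (geom@rb^2 - geom@rm^2) / 2, tolerance = 1e-6)
})

test_that("multi-component equilibrium is the y-weighted profile sum", {
  omega <- rpmToOmega(10000)
  z1 <- equilibriumProfile(lysLike(), geom, omega, 293.15)$z
  z2 <- equilibriumProfile(fibLike(), geom, omega, 293.15)$z
  mix <- 0.65 * z1 + 0.35 * z2
  # mixture stays normalised because each term is
  r <- equilibriumProfile(lysLike(), geom, omega, 293.15)$radii
  expect_equal(mix[1] * 0 + sum(mix), sum(0.65 * z1) + sum(0.35 * z2))
  expect_true(all(mix > 0))
})

test_that("boundary regression inverts the exponential drift law exactly", {
  omega <- rpmToOmega(40000)
  tt <- seq(0, 14400, length.out = 6)
  for (s in c(0.5, 1.91, 7.9, 20, 50)) {
    rr <- geom@rm * exp(s * 1e-13 * omega^2 * tt)
    track <- new("BoundaryTrack", times = tt, boundaryRadii = rr)
    est <- estimateSFromBoundary(track, omega)
    expect_equal(est@estimatedS, s, tolerance = 1e-10)
  }
  short <- new("BoundaryTrack", times = 0, boundaryRadii = geom@rm)
  expect_error(estimateSFromBoundary(short, omega), "two")
})

test_that("boundary location finds half-plateau crossings", {
  run <- svRun(nScans = 5, tRun = 14400)
  cmp <- lysLike()
  # ideal steps on the bin grid
  ss <- analyticScanSet(function(r, t)
    noDiffusionProfile(cmp, geom, omega40, t,  radii = r)$z,
    times = run@scanTimes, run = run)
  track <- locateBoundary(ss)
  chi <- (geom@rb - geom@rm) / 100
  for (j in 2:5) {
    oracle <- geom@rm * exp(1.91e-13 * omega40^2 * run@scanTimes[j])
    expect_lt(abs(track@boundaryRadii[j] - oracle), chi)
  }
  # symmetric sigmoid: the crossing is the inflection radius
  sig <- analyticScanSet(function(r, t) 0.9 * pnorm(r, 6.45, 0.05),
                         times = c(0, 100))
  tr2 <- locateBoundary(sig)
  expect_lt(abs(tr2@boundaryRadii[2] - 6.45), chi)
  # an equilibrium-shaped profile has no plateau to reference
  eq <- analyticScanSet(function(r, t)
    equilibriumProfile(fibLike(), geom, rpmToOmega(20000), 293.15,
                       radii = r)$z, times = c(0, 100))
  expect_error(locateBoundary(eq), "plateau")
})

test_that("s estimated from a simulated velocity run matches the input", {
  run <- svRun(nScans = 7)
  setts <- SimulationSettings(nPart = 2e5, nSteps = 20, nBins = 100,
                              seed = 31)
  ss <- simulateSample(list(lysLike(1)), geom, run, setts)
  est <- estimateSFromBoundary(locateBoundary(ss), omega40)
  expect_equal(est@estimatedS, 1.91, tolerance = 0.03)
})
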