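# Shared fixtures: a standard 12-mm solution column and the two reference
# solutes (lysozyme-like and fibrinogen-like) used throughout the tests.

testGeometry <- function() CellGeometry(6.0, 7.2)

svRun <- function(tRun = 28800, nScans = 11, rpm = 40000)
  RunConditions(rpm, 293.15, tRun = tRun,
                scanTimes = seq(0, tRun, length.out = nScans))

seRun <- function(tRun = 360000, nScans = 11, rpm = 10000)
  RunConditions(rpm, 293.15, tRun = tRun,
                scanTimes = seq(0, tRun, length.out = nScans))

lysLike <- function(y = 1) SoluteComponent(s = 1.91, buoyantMw = 4250,
                                           signalFraction = y)
fibLike <- function(y = 1) SoluteComponent(s = 7.9, buoyantMw = 97350,
                                           signalFraction = y)

# A small scan set on the standard geometry, built from an analytic profile
# matrix evaluated on the bin midpoints.
analyticScanSet <- function(f, times, nBins = 100, geometry = testGeometry(),
                            run = NULL, z0 = 1) {
  radii <- binMidpoints(geometry, nBins)
  z <- vapply(times, function(t) f(radii, t), numeric(length(radii)))
  ScanSet(radii, times, z, z0 = z0, geometry = geometry, run = run)
}
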