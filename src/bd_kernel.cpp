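#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian-dynamics trajectory kernel for one solute component.
//
// Particles start at `positions` (cm) and are advanced through the step grid
// `stepTimes` (strictly increasing, seconds, stepTimes[0] is the start time).
// One step: exact centrifugal drift r <- r * exp(s w^2 dt), plus the
// geometric (radial-metric) drift D dt / r required for consistency with
// the cylindrical-coordinate diffusion operator of the sector cell, plus a
// Gaussian Brownian displacement of variance 2 D dt, then specular
// reflection at the meniscus rm and bottom rb (folded repeatedly until
// inside the cell).  Without the D/r term the stationary particle density
// would be exp(sigma r^2/2) instead of the correct r exp(sigma r^2/2).
// Occupancy over nBins equal radial bins of [rm, rb] is recorded at the grid
// points flagged in `record` (1-based indices into stepTimes).
//
// Uses R's RNG stream (norm_rand), so results are reproducible under set.seed
// and the per-step draw order is fixed: particle 1..N at each step.
//
// [[Rcpp::export(name = ".bd_kernel")]]
IntegerMatrix bd_kernel(NumericVector positions,
                        double sSI,       // sedimentation coefficient, seconds
                        double D,         // diffusion coefficient, cm^2/s
                        double omega2,    // squared angular velocity, rad^2/s^2
                        NumericVector stepTimes,
                        IntegerVector record,
                        double rm, double rb, int nBins,
                        bool brownian) {
  const int nPart = positions.size();
  const int nGrid = stepTimes.size();
  const int nRec = record.size();
  const double chi = (rb - rm) / nBins;

  IntegerMatrix counts(nBins, nRec);
  std::vector<double> r(positions.begin(), positions.end());

  // record[] must be visited in increasing order
  int recPos = 0;
  for (int g = 0; g < nGrid; ++g) {
    if (g > 0) {
      const double dt = stepTimes[g] - stepTimes[g - 1];
      const double drift = std::exp(sSI * omega2 * dt);
      const double sd = (brownian && D > 0.0) ? std::sqrt(2.0 * D * dt) : 0.0;
      const double gdt = (brownian && D > 0.0) ? D * dt : 0.0;
      if (sd > 0.0) {
        for (int p = 0; p < nPart; ++p) {
          double x = r[p] * drift + gdt / r[p] + sd * norm_rand();
          while (x < rm || x > rb) {          // specular reflection, folded
            if (x < rm) x = 2.0 * rm - x; else x = 2.0 * rb - x;
            if (!std::isfinite(x)) stop("non-finite particle position");
          }
          r[p] = x;
        }
      } else {
        for (int p = 0; p < nPart; ++p) {
          double x = r[p] * drift;
          while (x < rm || x > rb) {
            if (x < rm) x = 2.0 * rm - x; else x = 2.0 * rb - x;
            if (!std::isfinite(x)) stop("non-finite particle position");
          }
          r[p] = x;
        }
      }
    }
    if (recPos < nRec && record[recPos] == g + 1) {
      int *col = &counts(0, recPos);
      for (int p = 0; p < nPart; ++p) {
        int i = (int)((r[p] - rm) / chi);
        if (i >= nBins) i = nBins - 1;   // r == rb lands in the last bin
        if (i < 0) i = 0;
        ++col[i];
      }
      ++recPos;
    }
  }
  if (recPos != nRec) stop("record indices outside the step grid");
  return counts;
}
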