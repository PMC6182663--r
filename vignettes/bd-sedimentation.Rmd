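---
title: "Particle-level simulation and global fitting of sedimentation experiments"
author: "sedbd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-level simulation and global fitting of sedimentation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedbd)
```

## The model

In an analytical ultracentrifuge a solute particle at radius $r$ experiences
the centrifugal force $m^{(b)}\omega^2 r$, where
$m^{(b)} = m(1 - \bar v \rho)$ is the buoyant mass. Balancing this against
viscous friction defines the sedimentation coefficient
$s = v/(\omega^2 r)$ (in Svedberg, $1\,\mathrm{S} = 10^{-13}\,\mathrm{s}$),
so the purely convective motion integrates to
$r(t') = r(t)\exp[s\omega^2(t'-t)]$. Diffusion opposes the concentration
gradient that sedimentation builds up; the Svedberg relation ties the two
transport coefficients to a single pair of molecular quantities:

$$ D = \frac{R T s}{M^{(b)}} . $$

Classically the interplay is described by the Lamm partial differential
equation in the sector-shaped cell. This package instead represents the
solute by a large number $N_\mathrm{part}$ of independent particles and
advances each of them with a Brownian-dynamics step,

$$ r(t + \Delta t) = r(t)\,e^{s\omega^2\Delta t} + \frac{D\,\Delta t}{r(t)}
   + \Delta r_\mathrm{brow}, \qquad
   \langle \Delta r_\mathrm{brow}^2 \rangle = 2 D \Delta t , $$

with specular reflection at the meniscus $r_m$ and the cell bottom $r_b$
(zero net flux). The drift factor is the exact integral of the convective
motion, so the step length is limited only by boundary effects, not by the
usual stability constraints of grid solvers. The second term is the
geometric (radial-metric) drift: writing the cylindrical-coordinate
diffusion operator as a Fokker–Planck equation for the radial particle
density $n(r) = r\,c(r)$ produces an outward drift $D/r$ in addition to the
sedimentation term. Without it, a reflected random walk in $r$ equilibrates
to a density $\propto e^{\sigma r^2/2}$ instead of the correct
$r\,e^{\sigma r^2/2}$, which biases low-speed (equilibrium) profiles by
roughly $1/(\sigma r^2)$ — about 10 % under the conditions used here. The
term is part of the diffusive dynamics and is disabled together with the
Brownian displacement in the no-diffusion limit.

Initial positions sample the uniform loading concentration of a sector
cell, whose radial density is $\propto r$:
$r_0 = \sqrt{u\,(r_b^2 - r_m^2) + r_m^2}$ with $u$ uniform on $(0,1)$.
Occupancies $n(i,j)$ over $N_r$ equal radial bins, recorded at each scan
time, convert to detector signal through the sector normalisation

$$ \frac{z(r_i, t_j)}{z_0} =
   \frac{r_b^2 - r_m^2}{2\chi}\,\frac{1}{r_i}\,
   \frac{n(i,j)}{N_\mathrm{part}}, \qquad \chi = \frac{r_b - r_m}{N_r}, $$

so an initially uniform sample reads $z/z_0 = 1$ in every bin.

### Heterogeneous samples

A mixture of $n_c$ non-interacting components is characterised by trios
$(s_k, M^{(b)}_k, y_k)$, where $y_k$ is the fraction of the loading signal
contributed by component $k$. When all specific signal constants are equal,
$y_k$ reduces to the weight fraction (mass-proportional detection,
absorbance/interference) or the number fraction (molar-proportional
detection); `signalFractions()` implements the general
$y_k \propto q_k c_{0,k}/M_k^{\alpha_k}$ form. Components are simulated
independently and their signals added. The particle budget is divided as
$\phi_k \propto y_k^{2/3}$, which balances the per-component counting noise
contributions to the summed signal.

## Simulation noise

The binned signal carries counting noise with standard deviation
$\propto 1/\sqrt{N_\mathrm{part}}$ for fixed bins, and grows as bins get
narrower ($n$ per bin shrinks). `estimateNoise()` quantifies it directly by
replicating a simulation over seeds and reporting the pointwise standard
deviation and its mean over the cell interior. Statistics exclude 0.2 cm
next to the bottom (the region dominated by discretisation end effects and
routinely discarded in experimental analysis) and two bins at the meniscus.
For two components at $y = 0.6/0.4$ on 100 bins, the interior noise of
$z/z_0$ is about $1\times10^{-2}$ at $N_\mathrm{part} = 10^6$ and scales as
$N_\mathrm{part}^{-1/2}$ over at least $10^4$–$10^7$ (the test suite fits
the log–log slope). A single number to remember: halving comes at four
times the particles.

## Reference (oracle) solutions

Two closed forms anchor the engine's correctness:

* **No-diffusion limit** (`noDiffusionProfile`): a sharp step at
  $r_\mathrm{bnd} = r_m e^{s\omega^2 t}$ with plateau
  $e^{-2 s \omega^2 t} = (r_m/r_\mathrm{bnd})^2$, the radial-dilution
  square law of the sector cell. With the Brownian term disabled the
  simulated boundary and plateau must (and do) reproduce this to binning
  accuracy.
* **Sedimentation equilibrium** (`equilibriumProfile`): the zero-net-flux
  profile $c(r) \propto e^{\sigma(r^2 - r_m^2)/2}$ with
  $\sigma = M^{(b)}\omega^2/(RT)$, normalised so the sector-weighted
  integral matches the loading. `equilibriumBinFractions()` integrates it
  exactly over bins for chi-squared comparison with long-run occupancies,
  and `sampleEquilibriumPositions()` draws from it by inverse transform for
  fixed-point tests.

`locateBoundary()` estimates per-scan boundary positions as half-plateau
crossings (the plateau is the median over the last interior quarter of the
cell; scans whose plateau window is contaminated by the boundary's
diffusion tail are skipped), and `estimateSFromBoundary()` regresses
$\ln r_\mathrm{bnd}$ on $t$ — the classical boundary-slope estimate of $s$.

## Global fitting

`fitNComponents()` recovers the $3 n_c - 1$ free parameters (one $y$ is
fixed by $\sum_k y_k = 1$) by minimising the dimensionless square deviation

$$ \Delta^2 = \sum_e W_e\,\Delta_e^2, \qquad
   \Delta_e^2 = \overline{\left[z_\mathrm{calc} - z_\mathrm{obs}\right]^2}
   \,/\,z_0^{(e)2} $$

averaged over the compared $(r_i, t_j)$ points of each experiment (the
0.2 cm bottom margin is excluded by default; weights default to uniform).
Every objective evaluation re-simulates all experiments with the candidate
parameters. Three numerical choices matter:

* **Common random numbers.** The simulation seed is held fixed across
  evaluations, so $\Delta^2$ is a deterministic, effectively smooth
  function of the parameters — a requirement for the Nelder–Mead simplex,
  which cannot average away evaluation noise.
* **Simplex restarts.** Parameters are searched in log space ($\log s_k$,
  $\log M^{(b)}_k$, softmax-transformed $y$). A single Nelder–Mead run on
  this surface tends to collapse before reaching the optimum when started
  far away (e.g. from the half/twice expansion initialisation); the search
  therefore restarts the simplex from the current best point until the
  objective stops improving (0.5 % relative, at most three restarts).
* **Multi-fidelity polish.** At search fidelity ($N_\mathrm{part} = 10^5$
  by default) the fixed noise realisation of the calculated profiles tilts
  the objective and biases weakly determined parameters — chiefly the
  buoyant mass of the faster component, whose diffusional signature is
  small. After the search, each parameter is refined by three-point
  parabolic steps in log space at 10× and then 30× the search fidelity
  (steps 0.12, 0.06, 0.04), followed by up to two further sweeps over the
  buoyant-mass coordinates alone — the softest directions, which move
  farthest under the search-fidelity bias. The reported $\Delta^2$ is
  finally re-evaluated once at $10^7$ particles with a fresh seed, so it
  reflects the data's noise rather than the fit machinery's.

`fitAuto()` implements the heuristic model expansion: first a
single-component fit (its starting point is derived from the data — $s$
from the boundary slope of the fastest experiment, $M^{(b)}$ via the
Svedberg relation from the boundary-spread growth $\mathrm{sd}^2 = 2Dt$ —
with a mid-range fallback of 5 S / 50,000 Da); then the component with the
largest signal fraction is split into children at half and twice its
$(s, M^{(b)})$, sharing its $y$ equally, and the larger model is accepted
only if it improves $\Delta^2$ by at least a factor 2 (model comparisons
use the search-fidelity objective under the same seed, so they are directly
comparable; the accepted model is polished last). For one component the
expansion rule is exactly the classical half/twice initialisation with
$y_1 = y_2 = 0.5$. The factor-2 acceptance threshold is this package's
rule; a more conservative or liberal analyst can change
`improvementFactor`.

## Study conditions and problem sizes

The worked example and the acceptance pipeline use a 12-mm solution column,
$r_m = 6.0$ cm to $r_b = 7.2$ cm, at 293.15 K, with two components:
1.91 S / 4250 Da at $y = 0.65$ (lysozyme-like) and 7.9 S / 97,350 Da at
$y = 0.35$ (fibrinogen-like). Two experiments are fitted globally: a
sedimentation-velocity run (8 h at 40,000 rpm, 11 scans, 20 time steps) and
an approach-to-equilibrium run (100 h at 10,000 rpm, 11 scans, 100 time
steps — low-speed runs are more sensitive to the step count near the
meniscus, so they get more steps; the bottom region, where step-count
artefacts concentrate, is masked in all comparisons). Synthetic data are
generated at $N_\mathrm{part} = 10^6$ per experiment on 100 bins; the fit
searches at $10^5$. With these sizes a full auto fit takes a few minutes on
one core; equilibrium and no-diffusion oracle checks run in seconds.

Under these conditions the fitted profiles match the synthetic data with a
global $\Delta^2$ of about $7\times10^{-5}$ (relative rms deviation about
0.85 % of the loading signal) — which equals, to within the calculation
side's small contribution, the counting noise of the $10^6$-particle data
themselves ($\Delta^2 \approx 6.5\times10^{-5}$ at the true parameters):
the fit exhausts the information in the scans. The recovered parameters
are accurate to a few tenths of a percent in both $s_k$, about 2 % in
$M^{(b)}_k$ (the fast component's buoyant mass is the softest direction)
and below 0.01 in $y_k$.

## What the generator does and does not emulate

The synthetic scan sets reproduce the counting statistics of a
particle-level simulation, radial dilution, diffusional boundary spreading
and multi-component superposition; `addMeasurementNoise()` can add
Gaussian detector noise on top (clipped at zero, seed recorded). They do
not contain time-invariant or radially structured instrument baselines,
meniscus optical artefacts, rotor acceleration phases, solution
compressibility, or any concentration dependence of $s$ and $D$
(non-ideality and interacting systems are out of scope; flotation is
rejected). Passing tests therefore validate the transport model and the
estimation machinery, not robustness to instrument systematics of real
XL-I data.

## Degenerate inputs and numerical details

Reflection is folded repeatedly, so even a displacement many cell widths
long (possible at extreme $D\,\Delta t$) lands inside $[r_m, r_b]$ and
particle number is conserved exactly at every scan. Radii at exactly $r_b$
bin into the last bin. Scan times are merged into the base step grid with a
relative tolerance of $10^{-9}$, each interval optionally subdivided
(`substepsPerScan`). Component RNG streams are derived deterministically
from the root seed (a seeded `sample.int` draw per component), so results
are bit-reproducible and independent of component evaluation order.
Savitzky–Golay smoothing defaults to an 11-point window of order 2 — common
dcdt practice; the time derivative differences raw consecutive scans at
interval midpoints, since cross-scan differencing already averages many
particles (pre-smoothing is optional). Boundary location requires a flat
plateau (IQR/median below 10 % in the plateau window) and raises an
analysis error on equilibrium-shaped profiles, which have none.

## Known limitations

* $M^{(b)}$ of fast, low-$D$ components is intrinsically weakly determined
  by velocity data and carries the largest uncertainty (several percent
  here even at $10^6$-particle data).
* The Nelder–Mead search with restarts is robust but not fast; a fit
  re-simulates the experiments thousands of times.
* The bottom 0.2 cm is systematically distorted at small step counts
  (time discretisation, as with any long-step scheme); increase `nSteps`
  if that region matters.
* The XL-I writer/reader implements one fixed dialect (with tolerance for
  a trailing third column); exotic instrument variants are not chased.
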