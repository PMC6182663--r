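Package: sedbd
Title: Brownian Dynamics Simulation and Global Fitting of Analytical
    Ultracentrifugation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sedimentation velocity and sedimentation equilibrium
    concentration profiles for heterogeneous, non-interacting solutes in a
    sector-shaped analytical ultracentrifuge cell by Brownian dynamics
    particle simulation (centrifugal drift plus Einsteinian diffusion steps
    with reflecting meniscus/bottom boundaries), and recovers per-component
    sedimentation coefficients, buoyant molecular weights and signal
    fractions from one or more scan sets by global Nelder-Mead least-squares
    fitting with heuristic model expansion. Includes Savitzky-Golay
    smoothing and dcdt-style derivatives, closed-form no-diffusion and
    equilibrium reference profiles, and readers/writers for Beckman
    XL-I-style scan files and CSV scan matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    Rcpp,
    signal,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
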