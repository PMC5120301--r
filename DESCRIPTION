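Package: swdfield
Title: Thalamocortical Neural Field Model of Epileptic Spike-Wave Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and dynamical analysis of a five-population
    thalamocortical neural field model of absence epilepsy. The cortical
    module carries an excitatory pyramidal population and two inhibitory
    interneuron populations with fast (GABA-A like) and slow (GABA-B like)
    time scales; the thalamic module carries relay and reticular populations
    with linearised activation. Provides a fixed-step fourth-order
    Runge-Kutta integrator with pulse-stimulation protocols, spectral and
    extrema-based classification of firing regimes (tonic, spike-wave
    discharge, clonic, saturated), one- and two-parameter state scans,
    double-pulse initiation/termination maps, and numerical bifurcation
    analysis of the equilibrium branch (Hopf detection via Jacobian
    eigenvalues, fold-of-cycles localisation via inherited-state sweeps,
    bistable-interval reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
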