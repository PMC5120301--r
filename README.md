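# swdfield

Simulation and dynamical analysis of a thalamocortical neural mass model of
epileptic spike-wave discharges (SWD), the ~2–4 Hz rhythm of absence
seizures.

The model couples a cortical circuit — an excitatory pyramidal population
PY and two inhibitory interneuron populations, a fast GABA<sub>A</sub>-like
IN<sub>1</sub> and a slow GABA<sub>B</sub>-like IN<sub>2</sub> — to a
thalamic relay/reticular (TC/RE) loop. With f(x) = 1/(1 + ν<sup>−x</sup>)
the sigmoid firing-rate function and s(x) = αx + β the linearised thalamic
activation:

```
PY'  = τ1 (ε1 − PY  + k1 f(PY) − k2 f(IN1) − k3 f(IN2) + k4 f(TC))
IN1' = τ2 (ε2 − IN1 + k5 f(PY) − k6 f(IN2))
IN2' = τ3 (ε3 − IN2 + k7 f(PY) − k8 f(IN1))
TC'  = τ4 (ε4 − TC  − k9 s(RE) + k10 f(PY))
RE'  = τ5 (ε5 − RE  − k11 s(RE) + k12 s(TC) + k13 f(PY))
```

At the reference couplings (k4, k10) = (1, 3) the system is bistable: the
low-saturated background state coexists with a ~3 Hz spike-wave limit
cycle, so a single hyperpolarising pulse on the cortical variables can
initiate a seizure and a second, weaker pulse can abate it. The package
provides:

* a fixed-step RK4 integrator (1 ms, compiled) with state-jump and
  rectangular-pulse stimulation protocols and linear parameter ramps;
* spectral/extrema classification of the firing regimes — tonic (~15 Hz),
  SWD, clonic, low/high saturated;
* 1-D and 2-D parameter scans, double-pulse initiation/termination maps of
  the (I, T) plane, and bisection threshold searches;
* numerical bifurcation analysis: equilibrium continuation with Jacobian
  eigenvalues, Hopf detection with criticality probing, fold-of-cycles
  localisation by inherited-state sweeps, and bistable-interval reporting.

Everything is deterministic — there is no random number generation
anywhere — so repeated runs are byte-identical.

## Worked example

```r
library(swdfield)
p <- load_preset("taylor2016-default")$params

# background at the reference operating point
quiet <- simulate_field(p)
cat("no stimulus :", classify_trajectory(quiet), "\n")

# a single hyperpolarising pulse at t = 20 s initiates a seizure
tr <- simulate_field(p, sim_config(duration = 50), stim_event(20, 0.3))
cat("after pulse :", classify_trajectory(tr),
    sprintf("(%.2f Hz)", dominant_frequency(cortical_mean(tr, from = 25))), "\n")

# a weaker second pulse at t = 35 s abates it again
cat("double pulse:", double_pulse_outcome(p, I = 0.3, T_amp = 0.2), "\n")

# the smallest initiating magnitude
thr <- threshold_search(function(m) {
  run <- simulate_field(p, sim_config(duration = 50), stim_event(20, m))
  classify_trajectory(run) == "SWD"
}, 0, 0.5, resolution = 0.005)
cat("initiation threshold:", round(thr$threshold, 2), "\n")

# the bifurcation skeleton behind the bistability
locate_hopf(p, "k4", c(0.5, 0.9))
locate_hopf(p, "k4", c(1.0, 1.3))
```

prints

```
no stimulus : SATURATED_LOW
after pulse : SWD (2.96 Hz)
double pulse: D
initiation threshold: 0.26
HOPF_SUPER at parameter value 0.7008 (bracket [0.7000, 0.7016])
HOPF_SUB at parameter value 1.1424 (bracket [1.1418, 1.1430])
```

The unstimulated run settles to the background resting state; the pulse
switches it onto the spike-wave attractor at ~3 Hz; outcome `D` of the
double-pulse protocol means the seizure was both initiated and terminated;
0.26 is the smallest pulse magnitude that crosses the separatrix; and the
two Hopf points bracket the bistable window on the k4 axis, whose lower
edge is the fold of cycles near 0.99 (`locate_cycle_fold()`).

A command-line front end over the same functions ships in
`inst/cli/swdfield.R` with subcommands `simulate`, `scan1d`, `map2d`,
`pulseplane`, `ramp` and `threshold`.

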