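---
title: "Modelling stimulus- and disinhibition-controlled spike-wave discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stimulus- and disinhibition-controlled spike-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdfield)
```

## The model

`swdfield` implements a five-population thalamocortical neural mass model of
absence epilepsy. The cortical module carries an excitatory pyramidal
population (PY) and two inhibitory interneuron populations: a fast,
GABA\(_A\)-like one (IN\(_1\)) and a slow, GABA\(_B\)-like one (IN\(_2\)).
The thalamic module carries the relay (TC) and reticular (RE) populations.
Writing \(f(x) = 1/(1 + \nu^{-x})\) for the sigmoid firing-rate function and
\(s(x) = \alpha x + \beta\) for the linearised thalamic activation, the
activities obey

\[
\begin{aligned}
\dot{PY}  &= \tau_1\,(\varepsilon_1 - PY + k_1 f(PY) - k_2 f(IN_1) - k_3 f(IN_2) + k_4 f(TC))\\
\dot{IN_1} &= \tau_2\,(\varepsilon_2 - IN_1 + k_5 f(PY) - k_6 f(IN_2))\\
\dot{IN_2} &= \tau_3\,(\varepsilon_3 - IN_2 + k_7 f(PY) - k_8 f(IN_1))\\
\dot{TC}  &= \tau_4\,(\varepsilon_4 - TC - k_9\, s(RE) + k_{10} f(PY))\\
\dot{RE}  &= \tau_5\,(\varepsilon_5 - RE - k_{11}\, s(RE) + k_{12}\, s(TC) + k_{13} f(PY)).
\end{aligned}
\]

All interneuron and reticular outputs enter with negative sign (inhibition),
all pyramidal and relay outputs with positive sign. Because \(\tau\)
multiplies the whole right-hand side, the very small \(\tau_3 = 26 \times
0.005\) makes IN\(_2\) the slow population, two orders of magnitude slower
than the fast interneurons (\(\tau_2 = 26 \times 1.25\)). The observable
used everywhere is the cortical mean \((PY + IN_1)/2\); IN\(_2\) is excluded
from the observable on account of its slow time scale. The reference
constants ship as the preset `taylor2016-default`
(`load_preset()`), with \(\nu = 2.5\times 10^5\), \(\alpha = 2.8\),
\(\beta = 0.5\) and the couplings listed in `field_params()`.

Two couplings organise most of the dynamics: \(k_4\) (TC \(\to\) PY, the
thalamic drive to cortex) and \(k_{10}\) (PY \(\to\) TC, the cortical drive
to thalamus). The reference operating point is \((k_4, k_{10}) = (1, 3)\),
where the system is bistable: a stable focus (the low-saturated background)
coexists with a large-amplitude \(\sim\)3 Hz spike-wave cycle.

### Grouped couplings

The two output couplings of one interneuron population strengthen together
in the disinhibition experiments: IN\(_2\)'s outputs \(k_3\) (to PY) and
\(k_6\) (to IN\(_1\)) form one group, IN\(_1\)'s outputs \(k_2\) (to PY) and
\(k_8\) (to IN\(_2\)) another. This is how the model expresses "the output
strength of a population" as a single knob, and it is the reading under
which the inhibition-induced SWD onset and the five disinhibition regimes
reproduce. Sweep functions therefore accept a character vector of parameter
names that are set jointly to each grid value, e.g.
`scan_1d(p, c("k3", "k6"), grid)`.

## Stimulation

A stimulation event perturbs the cortical variables PY and IN\(_1\) by
`direction * magnitude`, with negative direction by convention
(a hyperpolarising pulse; fixing the direction does not restrict the
analysis of this deterministic system). The default mode is an
instantaneous state jump — the perturbation moves the state across the
separatrix in state space, so what matters is where the state lands, not
how long the pulse lasts. A rectangular-pulse mode (contribution added to
the PY/IN\(_1\) derivatives over a configurable duration, default 0.05 s)
is retained as an option; thresholds shift somewhat between the two
conventions, and the jump convention is the one under which the published
initiation threshold (0.26) is recovered.

The canonical double-pulse protocol applies an initiation event at
\(t = 20\) s and a termination event at \(t = 35\) s of a 50 s run
(`double_pulse_outcome()`), classifying the window before the second event
and the final 10 s. Termination is phase-sensitive: whether a given
amplitude abates the discharge depends on where in the spike-wave cycle it
lands, so the terminating set is not an interval in the amplitude axis.
The weakest terminating amplitude over the initiation/termination plane is
attained just above the initiation threshold.

## Signal analysis and classification

Analysis always discards a transient (default 5 s of a 20 s run) and works
on the stationary tail. Three statistics drive the discrete labels:

* **peak-to-peak amplitude** from the stable local extrema (three-point
  comparison, plateaus collapsed);
* **dominant frequency**: the peak of the plain FFT periodogram of the
  mean-subtracted, untapered window (no taper, matching the model's
  noise-free, strongly periodic signals); windows of at least 10 s give a
  resolution of 0.1 Hz;
* **maxima per cycle**: the number of stable local maxima divided by the
  number of dominant periods in the window. A spike-wave cycle has a sharp
  spike plus a slow wave — at least two maxima per period — while a simple
  clonic (slow-wave) oscillation has one.

The decision rule of `classify_state()`: amplitude below `amp_tol`
(default `1e-3`) is *saturated*, split into `SATURATED_LOW` /
`SATURATED_HIGH` by the mean level against `level_threshold`; otherwise
frequency \(\ge\) 10 Hz is `TONIC` (the regime sits near 15 Hz); otherwise
a 1–5 Hz rhythm is `SWD` (two or more maxima per cycle) or `CLONIC` (one);
anything else — in practice only sub-1 Hz drifts — is `UNCLASSIFIED`, with
the full oscillation summary attached rather than a silent guess.

`level_threshold` defaults to 0.3: the low-saturated branch of the model
sits near a cortical mean of 0.15–0.18 and the high-saturated branch near
0.49–0.52, so any value between them separates the branches; 0.3 is the
midpoint. `amp_tol = 1e-3` cleanly separates the numerically-converged
focus (residual oscillations below \(10^{-6}\) after the transient) from
the smallest genuine limit cycles (amplitude above 0.05). One situation
needs a different tolerance: sliding windows over a *ramped* run drift with
the moving equilibrium by \(\sim 10^{-2}\) per 5 s window, so ramp analyses
pass `amp_tol = 0.02`.

## Sweeps, maps and thresholds

`scan_1d()` classifies the terminal window of one run per grid value, with
fixed initial conditions (the reference state
\((0.1724, 0.1787, 0.1803, -0.0818, 0.2775)\), which lies on the
non-seizure side of the separatrix in the first bistable window) or with
end states inherited forwards or backwards along the grid. Forward and
backward inherited scans disagree exactly inside bistable windows — the
hysteresis signature.

`state_map_2d()` pairs an unstimulated 20 s run with a pulsed 50 s run per
cell; cells whose quiet label is background but whose pulsed label is SWD
form the stimulus-induced-SWD region, cells with spontaneous SWD form its
monostable neighbour.

`threshold_search()` bisects a success predicate to a requested resolution
(default 0.005) after verifying the bracket. It is used for the initiation
amplitude, the spontaneous-SWD boundaries on the \(k_{10}\) axis, and the
inhibition-induced onset on the joint \(k_3 = k_6\) axis (resolution
0.001).

`ramp_simulation()` integrates a single long run with a linearly
time-varying coupling. For the regime-walk experiment the ramp spans 200 s
(rate 0.01/s for \(k_4: 0 \to 2\)); with that rate the recovered
label-change timings (about 126, 135 and 167 s for the onset of SWD,
clonic, and high-saturation) sit within a second of the published ones,
and reversing the ramp reverses the regime order. Ramp comparisons are
treated as qualitative (ordering), since the ramp rate is a modelling
choice.

## Numerical bifurcation analysis

The equilibrium branch is continued by pseudo-continuation
(`equilibrium_branch()`): each converged damped-Newton solve (analytic
Jacobian; step halving on residual increase, factor 0.5; residual
tolerance \(10^{-11}\)) seeds the next grid value. Stability comes from
the Jacobian spectrum; the analytic Jacobian uses
\(f'(x) = \ln(\nu) f(x)(1 - f(x))\) and is cross-checked against central
differences (step \(10^{-6}(1 + |x|)\)).

Hopf points are bisected on the real part of the leading complex eigenvalue
pair (default resolution 0.002). Criticality is decided by a probe
simulation on the unstable side: a supercritical Hopf grows its cycle like
\(\sqrt{\mu}\), so the attractor amplitude close to the crossing is about
half the amplitude four times further away; at a subcritical crossing the
trajectory lands immediately on the coexisting large cycle, so the two
probe amplitudes match.

Folds of limit cycles are located by inherited-state bisection
(`locate_cycle_fold()`): the cycle is tracked from the bracket end where it
exists, each probe simulation starting from the end state of the last run
that still had the cycle, settling 20 s before the amplitude is measured.
This simulation-based tracking resolves the fold locations to the 0.005
needed here without Floquet or collocation machinery; unstable cycles are
not tracked (their existence is inferred from the fold-plus-coexistence
structure). `bistable_intervals()` reports the grid intervals where a run
seeded at the continued equilibrium and a cycle-inherited run settle to
different labels — every reported interval is backed by explicit
coexistence, not by inference from eigenvalues.

On the \(k_4\) axis at \(k_{10} = 3\) this machinery recovers the skeleton:
supercritical Hopf near 0.70 (tonic cycle dies into the background focus),
fold of cycles near 0.99 (birth of the SWD cycle, opening the bistable
window), subcritical Hopf near 1.14 (focus loses stability; monostable
SWD), subcritical Hopf near 1.48 (focus returns; second bistable window
with the clonic cycle) and a second fold near 1.64 (oscillations die into
high saturation).

## Determinism, problem sizes and limitations

There is no randomness anywhere: fixed-step RK4 (1 ms, matching the
published temporal resolution) with fixed initial conditions makes every
table byte-reproducible, which is why run sidecars carry no seed. Single
50 s runs take tens of milliseconds (the integrator is compiled), so the
test suite and the acceptance script run full-length simulations — 20 s
background runs, 50 s double-pulse protocols, 30 s cycle-tracking probes,
a 200 s ramp — rather than shortened surrogates.

What these simulations emulate is the deterministic skeleton of the model:
regime boundaries, thresholds and bistability. They do not emulate
features of real EEG — no noise-driven state transitions, no spatial
structure or propagation, no parameter drift beyond the explicit ramps —
so passing checks validate the dynamical analysis, not clinical
applicability. Near the fold the model shows several-second excitable
transients, which is why termination windows are classified on the final
10 s of a run; landmark values quoted to two or three decimals are
grid/bisection outputs and inherit their stated resolutions.
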