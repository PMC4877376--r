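---
title: "Models and methods: AMPA/NMDA co-activation in dopaminergic neuron models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the two
dopaminergic-neuron models it implements, the firing-frequency
measurement convention, the numerical choices, and the design decisions
taken where the problem left them open.

## 1. Why these models

Midbrain dopaminergic neurons pace at 1–4 Hz through a subthreshold
Ca²⁺–K⁺ oscillation: a voltage-gated calcium current depolarizes the
cell, intracellular calcium accumulates and activates the SK
(small-conductance calcium-activated potassium) current, which
repolarizes it; calcium is then pumped out and the cycle repeats.
Spike-producing sodium and delayed-rectifier currents ride on top of
this oscillation without changing its period much, which justifies
models that omit them entirely and *register* a spike whenever the
voltage crosses a threshold — without resetting, so the oscillation
continues unperturbed.  That convention is used throughout:
`firing_summary()` counts upward threshold crossings (−0.4 in the
minimal model, −40 mV in the biophysical one) and reports their mean
rate as the firing frequency.

Both synaptic inputs are **tonic**: receptor activation is treated as a
constant (AMPAR) or voltage-dependent (NMDAR, magnesium block)
conductance with no kinetics.  This matches long receptor-agonist
applications in vitro and asynchronous background input in vivo, and it
is the regime in which AMPAR and NMDAR inputs have qualitatively
different effects — the question the package exists to study.  Pulsatile
or kinetic synaptic drive, repetitive-bursting (pause) mechanisms and
spike-shape reconstruction are out of scope.

## 2. The minimal model

`minimal_params()` builds the planar oscillator

$$c\dot v = f(v) + j_{KCa}(v,w) + j_{stim}(v), \qquad
  c\dot w = \epsilon\, g(v,w),$$

with $f(v) = a_1(v^3 + a_2v^2 + a_3v + a_4)$,
$j_{KCa} = g_{KCa}(E_K - v)\,w^4/(w^4 + k_{Ca}^4)$, and
$j_{stim} = g_N(v)(E_N - v) + g_A(E_A - v)$ where
$g_N(v) = g_N/(1 + M e^{-6v})$.  All quantities are dimensionless;
$c = 1.1\times10^{-4}$ calibrates time so that crossing rates are in
Hz.  Defaults: $\epsilon = 0.01$, $a_{1..4} = (-1, 1.35, 0.54, 0.0539)$,
$g_{KCa} = 0.5$, $E_K = -1$, $k_{Ca} = 10$, $k_w = -0.585$, $M = 0.2$,
$E_N = E_A = 0$, spike threshold $-0.4$.  Only $g_A, g_N \ge 0$ are
meant to be varied.

Design decisions worth recording:

* **The recovery branch switch.**  The recovery function is
  $g(v,w) = v - k_w$ for $w \ge 0$ and $0.01(v - k_w) - w$ for
  $w < 0$.  The SK gating term is even in $w$, so the folded
  v-nullcline has a mirror branch below the $v$ axis whose
  intersections with a naive w-nullcline could become stable equilibria
  and trap trajectories; the $-w$ pull-back term below the axis removes
  them.  The branch condition is on the sign of **w**, with the upper
  branch applying at exactly $w = 0$ (so $\dot w \ge 0$ on the axis
  whenever $v \ge k_w$).  Above the axis the w-nullcline is therefore
  the vertical line $v = k_w$, which is what `nullclines()` returns.
* **Two constants named alike.**  The parameter set contains two
  half-activation-like constants; the assignment used here —
  $k_w = -0.585$ in the recovery function, $k_{Ca} = 10$ in the SK
  current — is validated behaviourally: with it the unstimulated model
  paces in the tonic 1–4 Hz band, while the swapped assignment
  produces no oscillation at all (a regression test keeps this pinned).
* **One potassium reversal.**  The SK reversal is stored once as
  `e_k = -1`.
* **Observed w-range.**  Although the variables are nominally
  calibrated to order one, $k_{Ca} = 10$ forces the slow variable well
  above 1: on the tonic limit cycle $w$ spans roughly 0.1–9, and the
  stimulated equilibrium sits near $w^\ast \approx 8.6$.  The
  implementation follows the equations as given and simply documents
  this.
* **Absolute frequency scale.**  The time calibration is a pure
  rescaling: every frequency in the model scales as $1/c$.  With the
  default $c$ the tonic rate is 1.21 Hz and the NMDA-only ceiling is
  8.25 Hz; the *ratios* between regimes (tonic : NMDA-driven : AMPA-
  driven ≈ 1 : 6.8 : 2.1) are what the model pins down, and they are
  what the test suite asserts mechanistically.

## 3. The biophysical model

`bio_params()` builds the three-variable conductance-based model of
the README.  Component functions: the L-type activation
$g_{Ca}(v) = \bar g_{Ca}\,\alpha^4/(\alpha+\beta)^4$ with
$\alpha = 0.0032(v+50)/(1 - e^{-(v+50)/5})$ (removable singularity at
$-50$ mV evaluated by its limit) and $\beta = 0.05\,e^{-(v+55)/40}$;
the SK Hill function $\bar g_{KCa}\,[Ca]^4/([Ca]^4 + k_{Ca}^4)$; the
instantaneous potassium conductance as the Boltzmann sigmoid
$\bar g_K/(1 + e^{-(v+10)/7})$ (a divergent alternative reading of the
denominator would be singular at $-10$ mV and cannot limit the
voltage, which is this current's role); and the NMDA block factor
$1/(1 + 0.1[Mg]e^{-0.062v})$.  ERG gating uses
$n_\infty(v) = 1/(1 + e^{-(v+47.4)/2})$ — ERG is depolarization-
activated — and
$\tau_n(v) = 62 + 300\,[\sigma^-(v;-50.4) - \sigma^-(v;-63.4)]$ ms
written with *decreasing* sigmoids $\sigma^-$, the only sign convention
for which $\tau_n \ge 62$ everywhere and $\tau_n \to 62$ in both
voltage limits (the increasing convention would make the time constant
negative between the midpoints).

The calcium balance uses the surface-to-volume prefactor
$2\beta_{buf}/r$ (flux through the membrane of a cell of radius $r$,
buffered instantaneously with free-to-total ratio $\beta_{buf}$).  With
$v$ in mV, conductances in mS/cm², $r$ in cm, $F$ in C/mol and time in
ms the calcium rate comes out in µM/ms with conversion factor exactly
one, which the pure-pump-decay unit test pins down.  A small leak
$g_l(E_l - v)$ with its own reversal is included to limit the input
resistance; setting `g_l = 0` recovers the leak-free voltage equation
exactly.

### The shipped calibration

Only the ERG maximal conductance (2 mS/cm²) and the functional forms
above are fixed a priori; the remaining constants are a calibration,
shipped as `inst/extdata/bio_calibration.yaml` and read by
`bio_params()` (single source of truth — a test asserts the constructor
matches the file).  The calibration is **synthetic**: it was fitted,
once, so that the model exhibits the canonical behaviours of the cell
type, and then frozen:

1. tonic pacemaking at 3.5 Hz (inside 1–4 Hz) with a −88…−9 mV
   oscillation;
2. pacemaking persists (4.0 Hz) when the SK conductance is removed —
   the slow ERG current sustains it;
3. NMDAR input alone accelerates firing up to ≈47 Hz over
   $\bar g_{NMDA} \in [0, 12]$ mS/cm²;
4. AMPAR input alone gives only a small acceleration (≤ ≈6 Hz) and
   silences the cell (depolarization block) near
   $\bar g_{AMPA} \approx 0.04$ mS/cm²;
5. co-activation raises the attainable maximum to ≈70 Hz — a ≈50 %
   gain over the NMDA-only ceiling — and NMDAR input rescues firing
   from AMPA-induced block.

Two calibration levers matter most and are worth knowing about.  The
magnesium concentration (1.5 mM) sets the voltage at which the NMDA
block releases; at much lower values the NMDAR conductance is
substantially open at rest and behaves like an AMPAR conductance
(stabilizing instead of accelerating).  The pump rate and SK
half-activation jointly decouple the two rhythms: tonic pacemaking is
paced by the slow ERG/calcium cycle, while under NMDA drive the fast
calcium–SK loop takes over; a faster pump raises the NMDA-driven
ceiling but also the tonic rate, so both were set together.  Within
this calibration the depolarization-block boundary at
$\bar g_{AMPA} = 0.16$ mS/cm² is crossed back (firing rescued) only
for $\bar g_{NMDA} \gtrsim 10$ mS/cm²; the qualitative
rescue-by-NMDA property, not any particular coordinate, is what the
tests assert.

What the calibration does **not** emulate: spike shapes (no fast
sodium current), SK-blocker repetitive bursting, receptor kinetics,
dendritic structure.  Conclusions that pass the test suite are
statements about these ODE systems under tonic input, not about every
property of real DA neurons.

## 4. Dynamics measurements

`simulate_neuron()` integrates with `deSolve::lsoda` (adaptive,
stiffness-switching) against compiled right-hand sides, with dense
output every 1 ms-equivalent so no crossing is missed; compiled and
plain-R right-hand sides are cross-checked against each other in the
tests.  Defaults chosen once and used everywhere:

* duration 30 s / transient 10 s (minimal), 15 s / 5 s (biophysical) —
  the transient comfortably exceeds the slowest time constants, and
  the analysis window holds at least ten periods of the slowest
  reported rhythm;
* tolerances `rtol = atol = 1e-8`; halving them changes reported
  frequencies by far less than 1 % (asserted);
* initial state $(-0.7, 0.1)$ / $(-60\,\mathrm{mV}, 0.1k_{Ca},
  n_\infty(-60))$; steady frequencies are insensitive to a second,
  distant initial state (asserted), consistent with a single attractor
  in the firing region;
* firing requires at least 3 crossings; frequency is
  $(n-1)/(t_n - t_1)$, crossings located by linear interpolation;
* a non-firing trajectory is a **subthreshold oscillation** if its
  post-transient peak-to-trough exceeds 1 % of the
  threshold-to-trough excursion of the unstimulated model
  (0.0048 / 0.48 mV; `subthreshold_floor()` recomputes these and a
  test keeps them honest), else **quiescent** — rest or depolarization
  block.

## 5. Phase-plane analysis

The v-nullcline is inverted in closed form (the SK gating level is a
sigmoid in $w^4$), the w-nullcline is piecewise linear, and equilibria
reduce to one closed-form candidate above the axis plus a 1-D root
scan below it — no 2-D root polishing is needed.  The Jacobian is
analytic (the $w \ge 0$ branch derivative is used on the axis) and is
verified against central differences; eigenvalues come from base R's
`eigen`.

`hopf_boundary()` locates the Andronov–Hopf curve by bisection (to
1e-4 in conductance, below any plotted resolution) on the sign of the
leading eigenvalue's real part along the NMDAR axis.  Detection is by
linearization only; supercriticality is *verified empirically* rather
than assumed, by checking that oscillation amplitude collapses
continuously to zero at the boundary (`bifurcation_diagram()`).
Points whose scan shows no sign change — deep inside the firing region,
or where the boundary leaves the scanned NMDA interval (above
$g_A \approx 0.047$ for the default interval) — are omitted with a
message rather than extrapolated.  Where firing is lost without a
bifurcation (the limit cycle shrinking below threshold — "truncated"
regions), the regime map from the sweeps module, not extra bifurcation
machinery, describes the boundary.

## 6. Sweeps and the synergy summary

Default grids: $g_A \in [0, 0.06]$ step 0.002 and $g_N \in [0, 1.2]$
step 0.02 (minimal); $\bar g_{AMPA} \in [0, 0.4]$ step 0.02 and
$\bar g_{NMDA} \in [0, 12]$ step 0.25 (biophysical).  Every grid point
is simulated independently from the fresh default initial state — a
steady-response protocol; a parameter-continuation mode is available
through `frequency_map()`'s cache file but off by default.

`synergy_report()` compares the global maximum of the map with the
maximum on the $g_A = 0$ line and reports the percentage gain.  Both
maxima are refined inside their winning grid cells by golden-section
searches (`stats::optimize`; two rounds alternating the axes for the
joint maximum) because the peak is far flatter than the grid: in the
minimal model the frequency varies by less than 0.5 % over
$g_N \in [0.66, 0.84]$.  That flatness is a known limitation — the
*value* of the maximum and the synergy percentage are robust (grid
refinement moves them by well under 2 points), while the *coordinates*
of the argmax are intrinsically ill-conditioned and should be quoted
with that caveat.

## 7. Interfaces

Tabular results are tibbles and serialize to CSV; summaries to JSON;
configurations to flat YAML files (one key per parameter) validated by
the same constructors used programmatically.  The CLI
(`inst/cli/dasynergy`) is a thin wrapper over the exported functions:
`simulate`, `sweep` (resumable via a per-point cache file),
`phaseplane`, `report`.  Runs are deterministic: identical resolved
configurations produce byte-identical CSV payloads, and each run
directory contains its resolved `config.yaml` and package version.
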