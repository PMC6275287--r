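---
title: "Models, numerics and design choices in neurodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in neurodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

# The model class

neurodyn simulates conductance-based models: each compartment $i$ is an
isopotential patch of membrane obeying

$$C_i \frac{dV_i}{dt} = -\sum_j I_j,
\qquad
I_j = \bar g_j\, m_j^{p}\, h_j^{q}\,(V_i - E_j)\,A_i,$$

where $C_i = C_m A_i$ is the total capacitance, $\bar g_j$ a maximal
conductance *density* (µS/mm²), $E_j$ a reversal potential, and the gating
variables relax toward voltage-dependent steady states,

$$\tau_m(V)\,\dot m = m_\infty(V) - m, \qquad
\tau_h(V)\,\dot h = h_\infty(V) - h.$$

Units throughout: mV, ms, µM (calcium), µS/mm², mm², nA; synaptic and
gap-junction conductances in nS. Positive current is outward.

A model is a named tree — compartments containing conductances and
mechanisms, plus directed synapses — built functionally
(`add_compartment()`, `add_conductance()`, `connect()`, ...). Every
parameter and dynamic variable has a slash-separated path
(`"AB/NaV/gbar"`); serialization, snapshots and hashing all operate on the
canonical (lexicographically sorted) path order, which makes them
independent of construction order.

## Channel library

The built-in channels (NaV, CaT, CaS, ACurrent, KCa, Kd, HCurrent, Leak)
transcribe the classic sigmoidal parameterizations fitted to lobster
stomatogastric neurons that underlie a large family of published
single-compartment and network models. Two details matter:

* **KCa** has a calcium-dependent activation: the voltage sigmoid is
  multiplied by the saturating factor $\mathrm{Ca}/(\mathrm{Ca}+3\,\mu M)$.
* **CaT/CaS** are flagged as calcium channels: their current drives the
  calcium mechanism, and their reversal is not a free parameter but the
  Nernst potential recomputed from intracellular calcium every step
  (placeholder $+30$ mV before the first mechanism update).

Channels are registered with plain R functions for
$m_\infty, \tau_m, h_\infty, \tau_h$; registration validates that steady
states stay in $[0,1]$ and time constants stay positive on
$[-100, 100]$ mV, and rejects fractional exponents. Non-inactivating
channels ($q = 0$) allocate no $h$ state, so a compartment with the
8-channel set carries exactly $V$, Ca and 11 gating states — 13 dynamic
variables.

## Mechanisms

**Calcium buffering.** Intracellular calcium relaxes toward an
influx-shifted baseline,

$$\tau_{Ca}\,\dot{[Ca]} = -f\,I_{Ca} - [Ca] + Ca_0,$$

stepped with exponential Euler and clipped at 0. Defaults:
$\tau_{Ca} = 200$ ms, $Ca_0 = 0.05$ µM, $[Ca]_{out} = 3000$ µM,
$T = 11{}^\circ$C, $f = 14.96$ µM/nA. The $f$ value is the one used by the
cited single-compartment stomatogastric models for a 0.0628 mm² cell; it
produces calcium excursions of tens of µM in the bursting fixture. We kept
it because reducing $f$ by an order of magnitude (to force O(1–10) µM
excursions) weakens the calcium feedback enough that the burster
degenerates into tonic spiking — the calcium scale is part of what makes
this model burst.

**Integral control.** Each controller owns one conductance and integrates
the calcium error into an mRNA variable:

$$\tau_m^{ctl}\,\dot m_{RNA} = Ca_{tgt} - [Ca], \qquad
\tau_g\,\dot{\bar g} = m_{RNA} - \bar g,$$

with $\bar g$ floored at 0 while mRNA may go negative (as in the original
formulation). All regulation signs are positive. Within a time step the
calcium mechanism runs before the controllers, so controllers see the
updated calcium.

## Synapses

Graded chemical synapses follow
$s_\infty(V_{pre}) = 1/(1+\exp((V_{1/2}-V_{pre})/\Delta))$ with
$\tau_s = (1-s_\infty)/k_-$ and current
$I = \bar g\, s\,(V_{post}-E_{syn})$. The time constant is floored at
$dt$: as $s_\infty \to 1$, $\tau_s \to 0$ and the floor keeps the
exponential-Euler update finite while still snapping $s$ to its target —
$s$ remains in $[0,1]$ unconditionally. Two registered types differ only
in constants: Glutamatergic ($E_{syn} = -70$ mV, $k_- = 1/40$ ms⁻¹) and
Cholinergic ($E_{syn} = -80$ mV, $k_- = 1/100$ ms⁻¹); both use
$V_{1/2} = -35$ mV, $\Delta = 5$ mV. Electrical synapses are symmetric
ohmic couplings.

# Integrators

All solvers use a fixed step (default $dt = 0.05$ ms, output every step).

**Exponential Euler** (default) advances each linear-relaxation variable
exactly along its frozen-coefficient exponential:
$m \leftarrow m_\infty + (m - m_\infty)e^{-dt/\tau_m}$, and the voltage
toward $V_\infty = \sum g E^{*} / \sum g$ with
$\tau_V = C_m/\sum g$, where the sums fold in channel conductances,
graded-synapse conductances ($\bar g s / A$ toward $E_{syn}$) and
electrical couplings (toward the neighbor's previous voltage). Because
every update moves a state toward a bounded target, gating and synapse
variables stay in $[0,1]$ for any $dt$.

Update order within a step: synapse activations, then gating, then
voltage, then mechanisms — with all cross-compartment reads taken from
the previous step's values, so results do not depend on compartment
order. The calcium current fed to the mechanism is evaluated at the
pre-update state. These conventions (and the steady-state initialization
of gating variables at $V_0 = -60$ mV) are this package's own choices;
they remove startup transients and make runs bit-reproducible.

**Voltage clamp** pins $V$ and lets the gating variables evolve; the
reported clamp current is the total membrane current at the clamped
voltage — what the amplifier must inject. Clamp and current injection are
mutually exclusive per compartment.

**RK4** integrates the joint $(V, Ca, m, h)$ system of a single
compartment with the classical 4th-order scheme (inputs held
piecewise-constant over a step; states clipped to their domains after
each step). It exists as an accuracy cross-check of the default solver.

**Crank–Nicolson cable.** Unbranched chains with cylinder geometry
(radius, length in mm; axial resistivity in Ω·cm) are integrated by
solving the tridiagonal implicit-trapezoid voltage system (Thomas
algorithm) with gating staggered by exponential Euler. Axial conductances
come from half-cylinder resistances in series; `axial_g` can override
them. For a passive cable this scheme is genuinely second-order in time,
and its steady profile matches the analytic
$\cosh((L-x)/\lambda)/\cosh(L/\lambda)$ attenuation to well under 2% at
the fixture's discretization ($\lambda/\Delta x \approx 22$).

**Lookup tables.** Inside the compiled loop, gating curves are evaluated
by linear interpolation on a fixed grid ($-150..150$ mV at 0.05 mV),
built once per run from the registered R functions. The interpolation
error ($O(\Delta V^2)$, with $\Delta V = 0.05$ mV against sigmoid scales
of 5–20 mV) is orders of magnitude below the time-discretization error at
any tested $dt$. Outside the grid the endpoint value is used. Exact
function evaluation is used everywhere outside the inner loop
(`steady_state_curves()`, initial conditions).

**Failure handling.** A non-finite voltage aborts integration immediately
with the step index; traces are sampled every `out_dt` (a multiple of
`dt`).

# Protocol layer

* **Spike detection:** upward crossings of 0 mV with a 1 ms refractory —
  robust for both fixture spike shapes. Bursts group spikes with
  inter-spike intervals under 100 ms.
* **f–I curves** restart every amplitude from the same initial state and
  discard a 500 ms transient.
* **Activation recovery** reproduces the classic clamp experiment: steps
  spanning $-80..+50$ mV (500 ms each, asymptote = mean of the last 10%),
  $g(V) = I_\infty/(V - E)$, normalization by the maximum, and
  least-squares fits of $\left[1/(1+e^{(V_{1/2}-V)/k})\right]^n$ for
  $n = 1..8$. Because the data are normalized by their maximum over a
  finite voltage range (where the true curve is slightly below
  saturation), the fitted family is normalized identically — divided by
  its own value at the largest step. Without this, the ~2% normalization
  bias at $+50$ mV systematically favors a lower exponent; with it, the
  generating exponent fits exactly and $(V_{1/2}, k)$ are recovered to
  numerical precision. Fits use Levenberg–Marquardt with a fixed
  multi-start grid ($V_{1/2} \in \{-60,-40,-20,0\}$, $k \in \{5,15\}$),
  so the selected exponent is deterministic. Steps at the reversal
  potential are dropped (zero driving force).
* **Trajectory cost.** Two voltage traces are embedded as point clouds in
  the $(V, dV/dt)$ plane, binned on a shared $100\times100$ grid over
  $V \in [-80, 50]$ mV and a symmetric $dV/dt$ range taken from the
  *larger* of the two traces' extremes (this keeps the cost symmetric);
  the cost is the total absolute difference of the normalized
  histograms, in $[0, 2]$. Out-of-range points are clamped into edge
  bins, so no mass is lost.
* **Sweeps** set one uniquely-resolved parameter per value on a copy of
  the model; the baseline is never mutated.

# Fixtures: the study conditions

* `hh_neuron` — one 0.01 mm² compartment, NaV 1000 / Kd 300 / Leak 1
  µS/mm². Quiescent at rest; 0.2 nA of injected current elicits tonic
  spiking.
* `bursting_neuron` — one 0.0628 mm² compartment with the 8-channel set
  (NaV 1000, CaT 25, CaS 60, ACurrent 500, KCa 50, Kd 1000, HCurrent 0.1,
  Leak 0.099 µS/mm²) and the calcium mechanism; bursts at roughly 2 Hz
  with calcium oscillations phase-locked to bursts. Removing the
  mechanism freezes calcium and the cell spikes tonically.
* `homeostatic_neuron` — the same cell started at 10 µS/mm² on every
  controlled channel, with an integral controller on each conductance
  except Leak. Controller timescales follow the classic recipe
  $\tau_m^{ctl} \propto 1/\bar g^{tgt}$ (here $2\times10^6 / \bar
  g^{tgt}$ ms, $\tau_g = 5000$ ms), so the steady-state densities land in
  the burster's ratios. The default $Ca_{tgt} = 65$ µM is the bursting
  fixture's own time-averaged calcium — the value an integral controller
  of this cell should defend. Over a 200 s run the time-averaged calcium
  settles within a few percent of the target with all densities bounded.
* `pyloric_network` — the classic three-cell circuit (AB, LP, PY; each
  with the 8-channel set scaled per cell) coupled by seven graded
  synapses of the two types (AB→LP glut 30 + chol 30, AB→PY glut 10 +
  chol 3, LP→AB glut 30, LP→PY glut 1, PY→LP glut 30 nS). It produces the
  triphasic rhythm with AB → LP → PY burst onsets on every cycle.
* `passive_cable` — 50 leak-only compartments, 10 µm radius, 100 µm long,
  $R_a = 100$ Ω·cm, $R_m = 1$ MΩ·mm² ($\lambda \approx 2.24$ mm over a
  5 mm cable).

These generators emulate the canonical laboratory models of this
literature, not recordings: they are deterministic, have no channel
noise, no temperature dependence, no morphology beyond the unbranched
cable, and spike shapes specific to the transcribed kinetics. Tests that
pass on them certify the simulator's numerics and the implemented
dynamics — not that any parameter set fits a particular biological cell.

# Serialization, snapshots, hashing

`serialize_model()` flattens every parameter and dynamic variable into
one numeric vector in canonical path order; `deserialize_model()` is its
exact inverse (bit-identical round trip). Snapshots store the serialized
vector under a case-sensitive name inside the tree; restoring requires an
unchanged structure and, because integration is deterministic,
re-integration after a restore reproduces the original continuation
bit-for-bit.

Two MD5 hashes identify a model: the **structural hash** digests the
canonically ordered component types together with their registered
equation source text (the deparsed gating functions), so it is invariant
to construction order and parameter values but changes when any equation
changes; the **full hash** additionally digests the serialized vector
(doubles printed at 17 significant digits). Both are exposed rather than
guessing which one a given reproducibility workflow needs. Trace files
embed the generating model's full hash, and `validate_trace()` flags
mismatches.

YAML configs are written canonically (sorted keys, verbatim numerics at
17 significant digits) so `save(load(f))` is byte-identical and loaded
models hash identically to programmatically built ones.

# Problem sizes used by the test suite

The suite's long-running checks use: 2 s of the spiking fixture and 20 s
of the burster for the step-size/cost comparisons (reference
$dt = 0.0125$ ms, coarser runs at 0.2/0.1/0.05 ms) — the burster needs
~20 burst cycles for the occupancy histograms to average over phase
drift; 200 s for homeostatic convergence; 12 s for the pyloric rhythm;
500 ms per clamp step for activation recovery. These sizes were chosen as
the smallest that make the corresponding property stable, and they are
the sizes the claims in this vignette refer to.

# Known limitations

* Only unbranched cables; no branched morphologies or spatial calcium.
* No stochastic channels, temperature scaling, plasticity, or
  event-based (spike-triggered) synapses.
* RK4 is restricted to single compartments without synapses or
  controllers; voltage clamp is implemented in the exponential-Euler
  solver only.
* Custom channels with calcium-dependent activation must factor as
  (voltage sigmoid) × (saturating calcium term); arbitrary
  $m_\infty(V, Ca)$ surfaces are not tabulated.
* The compiled inner loop interpolates gating curves; pathological
  user-registered curves with sub-0.05 mV structure would be smoothed.
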