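---
title: "A Markov gating model of IKs and its pharmacological modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov gating model of IKs and its pharmacological modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iksim)
```

## The model

The slow delayed-rectifier potassium current IKs is carried by Kv7.1
channels in complex with KCNE1 beta-subunits.  `iksim` represents its
gating as a six-state Markov scheme

    C1 <-> C2 <-> C3 <-> O1 <-> O2
            |
           C2s

with three resting closed states `C1`, `C2`, `C3`, two conducting open
states `O1`, `O2`, and a stable ("inactivated") closed state `C2s`
branching from `C2`.  State occupancy `p(t)` evolves under the master
equation `dp/dt = p Q(V)`, where the generator `Q` collects the
transition rates at the clamped membrane voltage.

Every rate is an exponential function of the reduced membrane potential
`phi = V F / (R T)` (dimensionless; `V` in volts internally, supplied in
mV throughout the API):

| transition | forward | backward |
|---|---|---|
| `C1 <-> C2` | `alpha1 = exp(0.47 phi)` | `beta1 = 0.2 exp(-0.35 phi)` |
| `C2 <-> C3` | `alpha2 = 0.46 exp(0.47 phi)` | `beta2 = 3.3 exp(-0.35 phi)` |
| `C3 <-> O1` | `alpha3 = 24 exp(0.06 phi)` | `beta3 = 19 exp(-0.007 phi)` |
| `O1 <-> O2` | `epsilon = 4.6 exp(0.8 phi)` | `delta = 1.4 exp(-0.7 phi)` |
| `C2 -> C2s` | `gamma = 10` | `rho` (see below) |

all in s^-1.  The adamantane-class gating modifier acts through a single
parameter: the exit rate `rho` from the stabilized closed state is 10
s^-1 for drug-free channels and 0.1 s^-1 — exactly 100-fold smaller —
for drug-bound channels.  Macroscopic current is synthesized ohmically,
`I = Gmax * (p_O1 + p_O2) * (V - Erev)`.

Three design choices in this table were genuinely open and are isolated
in the scheme definition (a JSON document, see
`iks_scheme_file()`), so they can be swapped without code changes:

* **Edge-to-rate mapping.**  The assignment of the four rate pairs to
  the four reversible edges follows the listing order of the parameter
  set together with the explicitly stated direction of `rho`
  (`C2s -> C2`).  In particular `epsilon/delta` connect `O1 <-> O2`
  rather than `C3 <-> O1`.
* **Direction of `epsilon`.**  `epsilon` carries a positive effective
  charge (+0.8), so it is taken as the depolarization-favoured forward
  rate `O1 -> O2`.
* **Branch point of `C2s`.**  `C2s` attaches to `C2`, the state its
  name and the stated `C2s -> C2` direction imply.

## Temperature and physical constants

The reduced potential needs an absolute temperature, which protocols for
oocyte recordings rarely state precisely.  The default is `T = 293.15 K`
(20 degrees C, room temperature); across the 19–23 degrees C band typical of
such experiments `phi` varies by under 2%, below every effect size the
package asserts.  `phys_constants()` makes `T` (and `F`, `R`)
configurable, and the value used is serialized with every scheme.

## Solving the master equation

Voltage protocols are piecewise constant, so the solution on each
segment is exact: `p(t) = p(0) expm(Q t)`, evaluated by
eigendecomposition of `Q` once per (scheme, voltage) and applied lazily
to the whole output time grid.  If the eigenvector matrix is
ill-conditioned (reconstruction error above 1e-8) the code falls back to
a stiff ODE integrator (`deSolve::lsoda`, rtol 1e-10).  Two guards
protect probability semantics:

* States that are unreachable from the support of the initial occupancy
  along positive-rate edges are structural zeros of the solution and are
  pinned to exactly 0.  This makes degenerate configurations — e.g. the
  binding extension at zero ligand concentration — reproduce the
  reduced model exactly rather than to within roundoff.
* Entries in `(-1e-9, 0)` are clipped to 0 and each row renormalized;
  anything worse raises an error instead of being hidden.  The clip
  threshold matches the 1e-9 row-sum tolerance the package asserts
  everywhere; a tighter threshold (say 1e-12) sits below the roundoff
  floor of eigendecomposition-based propagation on the 12-state
  binding-augmented scheme over thousands of simulated seconds and
  would reject valid solutions.

The test suite cross-checks the matrix-exponential path against an
independent explicit-Euler integration.  One numerical fact is worth
recording: explicit Euler at `dt = 1e-5 s` on this generator (rates up
to ~40 s^-1 at +40 mV) carries a first-order global truncation error of
about 2e-6 in occupancy, peaking near t = 0.5 s of a +40 mV step.  The
difference between the two paths shrinks linearly in the Euler step
(2e-7 at `dt = 1e-6`), which identifies the residual as the reference's
truncation error, not a solver error; agreement tighter than ~2e-6
against a `dt = 1e-5` Euler reference is therefore not achievable by an
exact solver, and the tests document this bound.

Initial conditions follow experimental practice: the steady state at the
protocol's holding potential (`steady_state()`, the null vector of `Q`
normalized to unit mass), unless an explicit `p0` is given.  Between
sweeps, occupancy either re-equilibrates to the holding steady state
(IV-type protocols; the experimental inter-sweep interval of tens of
seconds justifies this) or carries over (repetitive, rest and
conditioning protocols, where the carry-over is the phenomenon under
study).  The sweep reset policy is a protocol attribute, not a
simulation flag, so a recording's provenance fully determines its
dynamics.

## Protocols and current synthesis

`preset_protocol()` ships the protocol library: 5 s steps from -40 to
+60 mV with -120 mV tails (`"fig9"`), 10 s steps from -100 to +60 mV
(`"activation_iv"`), deactivation tails from -140 to -40 mV after a
-20 mV prepulse (`"deactivation_tails"`), 7 s pulses to +40 mV every
30 s (`"repetitive_40"`), a 4.5 min rest at -80 mV (`"rest_hold"`), and
subthreshold conditioning trains at 2 or 0.2 Hz (`"conditioning"`).
Sampling defaults to 1 ms.  Overrides are explicit arguments — a
protocol never changes silently.

Default synthesis parameters: `Erev = -90 mV` (a typical K+ reversal
under ~4 mM external K+) and `Gmax = 1 uS`.  Every analysis the package
asserts on (normalized tails, fractional inhibition, time constants) is
invariant to `Gmax`, which the tests verify by linearity.

## The drug phenotype

`reproduce_fig9()` runs both configurations through the 5 s step
protocol and computes the full closed-state-stabilization signature:
the depolarizing shift of the tail-based Boltzmann activation curve
(about +24 mV under the defaults, computed fresh on every run), slowed
activation, voltage-dependent relief of end-pulse inhibition between
+20 and +60 mV, and near-invariant deactivation at -120 mV.

One subtlety deserves emphasis.  Because `gamma` and `rho` are both
voltage-independent, the stabilized state sits at its 100:1 equilibrium
with `C2` at *every* holding voltage; drug-slowed activation is a
trap-drainage phenomenon that only appears at depolarizations strong
enough to pull occupancy forward through the 0.1 s^-1 bottleneck.  At
-20 and 0 mV the fully-bound model predicts no slowing of the apparent
single-exponential time constant — the small untrapped pool relaxes
quickly to its (much reduced) quasi-steady current, and the fitted tau
is in fact *smaller* than control there.  Experimentally, slowed
activation is reported at test potentials where drug-inhibited currents
are measurable; the model reproduces slowing robustly from +20 mV
upward, and `reproduce_fig9()` asserts it over that range while
reporting the full per-voltage table.

## The curve-fitting toolkit

All four analysis equations of routine voltage-clamp work are
implemented as data-frame-first fitters returning a common `iks_fit`
object with `tidy()`/`glance()`/`autoplot()` methods:

* **Hill**: `I/Imax = 1 / (1 + (C/IC50)^H)`, fitted in log10
  concentration space (search interval 1e-11 to 1e-3 M) with `H`
  bounded to [0.2, 5] for numeric stability and physiological
  plausibility; `H` may be fixed.  The IC50 standard error is
  transformed from log space by the delta method.
* **Boltzmann**: `A(V) = Amin + (Amax - Amin)/(1 + exp((V1/2 - V)/k))`
  with box constraints (`k` in [0.5, 50] mV, `Amax` in [0.2, 2], `Amin`
  in [-0.5, 0.5]) that keep fits of unsaturated activation curves from
  diverging.
* **Single exponential**: `y = A0 + A exp(-t/tau)`; flat traces are
  flagged (`converged = FALSE`) rather than fitted.
* **Log-log linear**: OLS of `log10(tau)` on `log10(C)`; for
  pseudo-first-order binding the slope approaches -1 when `C >> Kd`.

Nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
with analytic starting values (midpoint/quantile heuristics) and up to
three restarts before a non-convergence flag is returned — never an
exception.  On noise-free self-generated data every fitter recovers its
generating parameters to better than 1e-6 relative error across the
parameter grids exercised in the test suite.

Two extraction conventions are deliberate choices where the analysis
description leaves latitude:

* **"Initial" tail amplitude** is read at the first sample 5 ms after
  the tail step (one settling interval past the instantaneous jump);
  a peak-within-50 ms alternative is available
  (`tail_activation_curve(method = "peak")`).
* **Activation fit window** excludes the first 200 ms of the test
  pulse: IKs activates sigmoidally, and a single exponential is a
  late-time description.  Deactivation fits skip 5 ms of settling.

## Synthetic data: what it emulates, what it does not

The generators exist so that every pipeline stage is testable without
recordings.  `synth_recording()` adds, per sample, ohmic leak
`g_leak (V - E_leak)`, optional slow contamination (first-order
activation, default tau 2 s, above +40 mV — mimicking endogenous
currents recruited by long strong depolarizations), and i.i.d. Gaussian
current noise.  `synth_dose_response()` scatters Hill-equation responses
multiplicatively (`sigma_rel` default 0.03, clipped to [0, 1.1]).  All
noise magnitudes are synthetic-fixture choices — the source experiments
report none — and every generator is a pure function of its parameters
and an integer seed.

What the generators do *not* emulate: capacitance transients and series
resistance, P/N leak subtraction artefacts, expression variability
between cells, and temperature drift.  Green tests on synthetic data
therefore certify the analysis chain (solver, extraction conventions,
fitters, seeded reproducibility) — not robustness to every artefact of
real oocyte recordings.

## The binding extension

The two-configuration model describes fully drug-free versus fully
drug-bound populations; concentration and time dependence need an
explicit binding graph.  `augment_with_binding()` doubles the scheme:
an unbound copy, a bound copy carrying the bound drug configuration,
and mass-action edges `kon * C` / `koff` between each binding-competent
state and its twin.  The competent set defaults to the closed states
(`C1`, `C2`, `C3`, `C2s`), reflecting closed-state drug access; `kon`
defaults to 1e4 M^-1 s^-1 with `koff = kon * 78.4e-9` so that the
dissociation constant equals a 78.4 nM IC50 surrogate.  Both are free
parameters — the source data constrain neither individually.

`synth_washin()` simulates drug application at t = 0 (unbound steady
state, zero bound occupancy) under a repetitive pulse train with
carry-over, and fits the normalized end-pulse amplitude series with a
single exponential to obtain `tau_inhibition` per concentration.  The
default train uses 1 s pulses to +40 mV every 5 s — denser than the
classical 7 s/30 s inhibition protocol — because wash-in rates across
0.1–10 uM at the default `kon` span roughly 10 to 600 s and a 30 s
sampling interval cannot resolve the fast end of that range.  Pulse
counts adapt to ~4 expected binding time constants per concentration
(bounded to [20, 500] pulses).  Across 0.1–10 uM the fitted
`tau_inhibition` decreases monotonically with concentration with a
log-log slope near -0.87: slightly shallower than the ideal -1 because
at 0.1 uM (only ~1.3 Kd) the concentration-independent `koff` still
contributes to the observed rate — exactly the pseudo-first-order
prediction `tau = 1/(kon C + koff)`.

## Problem sizes and reproducibility

The shipped analyses use deliberately moderate sizes: 1 ms sampling for
step protocols, 10 ms for wash-in; 27–30 parameter combinations per
fitter family in the round-trip grids; 200 seeded repetitions (5
replicates each, 3% scatter) for stochastic IC50 recovery; 5
concentrations for wash-in scaling.  Every random quantity flows from a
single integer seed (`withr::with_seed`), and recording metadata
(scheme, protocol, settings, noise, seed) is sufficient to regenerate
any output byte-identically — a property the tests assert.

## Known limitations

* Single-channel stochasticity (Gillespie simulation) is out of scope;
  everything is macroscopic and deterministic given the seed.
* No temperature scaling of rates (Q10); `T` enters only through `phi`.
* Rate constants are asserted, not fitted: there is no machinery for
  estimating Markov-model parameters from recordings.
* The fully-bound configuration stands in for saturating drug; partial
  occupancy requires the explicit binding extension rather than a
  fractional mixture of configurations.
* The Boltzmann box constraints, while necessary for unsaturated
  curves, mean pathological inputs can converge to a bound; fits report
  their constraints through `tidy()` standard errors and the
  `converged` flag rather than failing loudly.
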