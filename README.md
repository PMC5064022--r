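# iksim

Markov gating models, voltage-clamp simulation and curve fitting for
IKs channel pharmacology.

## The problem

The slow delayed-rectifier potassium current IKs, carried by
Kv7.1/KCNE1 channel complexes, shapes cardiac repolarization and is a
drug target with a difficult pharmacology: adamantane-class compounds
inhibit it with nanomolar potency not by plugging the pore but by
*modifying gating* — they stabilize a non-conducting closed state, which
produces incomplete maximal block, a depolarizing shift of the
activation curve, slowed activation, near-untouched deactivation, and
drug access to closed channels at rest.

`iksim` is for electrophysiologists and modellers who want to simulate
and analyse that mechanism quantitatively.  It provides:

* a six-state voltage-dependent Markov model of IKs gating
  (`C1 <-> C2 <-> C3 <-> O1 <-> O2`, plus a stabilized closed state
  `C2s` off `C2`), with every rate of the form
  `a * exp(z * V F / (R T))`.  Drug binding is a single parameter
  change: the `C2s -> C2` exit rate `rho` drops from 10 to 0.1 s^-1
  (100-fold);
* exact master-equation propagation (`dp/dt = p Q`, matrix exponential
  per constant-voltage segment) through a library of two-electrode
  voltage-clamp protocol presets, with ohmic current synthesis
  `I = Gmax * Popen * (V - Erev)`;
* an explicit ligand-binding extension (mass-action `kon C` / `koff`
  edges to a drug-bound copy of the scheme) for wash-in kinetics and
  concentration dependence;
* the four standard analysis fits — Hill concentration-response
  `1/(1 + (C/IC50)^H)`, Boltzmann activation
  `Amin + (Amax - Amin)/(1 + exp((V1/2 - V)/k))`, single-exponential
  kinetics `A0 + A exp(-t/tau)`, and log-log linear wash-in slopes —
  as tidyverse-style fitters with `tidy()`, `glance()` and
  `autoplot()` methods;
* seeded synthetic-data generators (noisy recordings with leak and an
  optional endogenous-current contaminant, Hill-scattered
  dose-response tables, wash-in series) so the whole pipeline is
  testable without recordings.

## Worked example

Simulate the drug-free and drug-bound model through the 5 s step
protocol (holding -80 mV, steps -40 to +60 mV, tails at -120 mV),
build normalized tail-current activation curves, fit Boltzmann
functions, and check the whole gating-modifier signature:

```r
library(iksim)
report <- reproduce_fig9()
report
#> <iks_fig9_report> simulated gating-modifier phenotype
#>   V1/2 control 19.09 mV, bound 43.45 mV (shift +24.35 mV)
#>   C2s->C2 rate ratio (free/bound): 100
#>   properties: 6/6 pass
#> # A tibble: 6 × 3
#>   property               value pass
#>   <chr>                  <dbl> <lgl>
#> 1 rho_ratio_100         100    TRUE
#> 2 delta_v_half_positive  24.4  TRUE
#> 3 activation_slowed       2.53 TRUE
#> 4 inhibition_relief       1    TRUE
#> 5 deactivation_spared     4.23 TRUE
#> 6 tails_normalized        1    TRUE
```

The half-activation voltage shifts by +24 mV under drug; end-pulse
inhibition is relieved with depolarization (`report$inhibition`);
activation slows where the stabilized state drains
(`report$activation_tau`) while deactivation at -120 mV barely moves
(`report$deactivation_tau`).  `autoplot(report)` draws both activation
curves with their fits.

Dose-response analysis on synthetic data:

```r
tbl <- synth_dose_response(ic50_M = 78.4e-9, hill = 1,
                           sigma_rel = 0.03, seed = 42)
fit <- hill_fit(tbl)
fit
#> <iks_fit> family 'hill' [free H], converged (n = 35, RSS = 0.005387)
#> # A tibble: 2 × 3
#>   term      estimate     std.error
#>   <chr>        <dbl>         <dbl>
#> 1 IC50  0.0000000810 0.00000000120
#> 2 H     1.04         0.0145
```

The generating IC50 of 78.4 nM is recovered as 81.0 ± 1.2 nM from 35
noisy replicates.  `autoplot(fit)` plots data and curve on a log
concentration axis.

Wash-in kinetics through the binding extension:

```r
w <- synth_washin(iks_scheme(), c(0.1, 0.3, 1, 3, 10) * 1e-6,
                  kon = 1e4, koff = 1e4 * 78.4e-9, seed = 1)
linear_log_fit(w$taus)        # slope ~ -0.87: pseudo-first-order binding
```

A thin command-line wrapper with subcommands (`simulate`, `fit`,
`synth`, `reproduce-fig9`, `fixtures`) lives at
`system.file("cli", "iksim.R", package = "iksim")`.

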