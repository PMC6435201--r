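---
title: "The charge-difference model of ionic homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The charge-difference model of ionic homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargediff)
```

## The model

`chargediff` simulates a single model cell — effective water volume
7.5×10⁻¹³ L (a 10 µm cube with 25% organelle volume), fixed membrane
capacitance 1.2×10⁻¹¹ F, temperature 309.85 K — bathed in a large reservoir
whose composition is constant except for explicitly scheduled buildups.
The state is the set of intracellular concentrations ([Na⁺]ᵢ, [K⁺]ᵢ,
[Cl⁻]ᵢ, an impermeant anion [An⁻]ᵢ of mean valence `z`, a neutral
impermeant osmolyte [osm]ᵢ), the membrane potential `Em`, the water volume
`vol`, and the cumulative ATP count.

The defining feature of the charge-difference approach is that `Em` is a
true state variable.  It is initialised by the user (0 V for symmetric
passive starts) and thereafter only ever incremented by `dQ/c`, where `dQ`
is the net charge carried across the membrane during one time step.  No
Goldman-type closure and no bulk-electroneutrality assumption enters the
dynamics; macroscopic electroneutrality *emerges*, because the charge
equivalent of physiological voltages (≈6×10⁶ ions at −80 mV) is osmotically
negligible (≈13 µM here), while any sustained imbalance produces a voltage
that feeds back on the fluxes within milliseconds.

Each step performs three calculation sets, in a fixed order that is part of
the method's identity (no sub-iteration, no operator splitting):

1. **Fluxes**, evaluated wholly from the beginning-of-step state.
   Conductive fluxes are linear in the electrochemical driving force
   (`gNa·(E_Na − Em)` etc.; `gCl·((RT/F)ln([Cl⁻]ₒ/[Cl⁻]ᵢ) + Em)` for the
   anion), not Goldman constant-field fluxes.  The Na⁺/K⁺-ATPase turns over
   at `Ap = Rp/(1 + hNa/[Na⁺]ᵢ)³` — third order in internal Na⁺, half-site
   occupation at `hNa` = 8 mM, saturating at the rate `Rp` — and moves `x`
   Na⁺ out and `y` K⁺ in per cycle.  The NKCC and KCC cotransporters are
   electroneutral and driven by the base-10 log of their concentration
   product ratios; their activities are linear in that driving force and
   unbounded, as no saturation is specified for them.
2. **Accumulation**: flux sums are multiplied by the step, converted to
   concentration changes through `dX/(vol·L)`, and buildups are applied
   (an internal-anion buildup is accompanied by Na⁺ at `−z` times its rate
   to keep the added material electroneutral).  Buildups never contribute
   to `dQ = (dNa + dK − dCl)·e`.
3. **Voltage and volume**: `Em ← Em + dQ/c`, then the osmotic ratio
   `osV = Σᵢ/Σₒ` is relaxed through `chV = 1 − (1 − osV)·VoR·st` and the
   volume and all five internal concentrations are rescaled by `chV`.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `gNa`, `gK`, `gCl` | ions s⁻¹ V⁻¹ | 0 | linear leak conductances; 2×10¹⁰ total = 3.2 nS = 312.5 MΩ input resistance |
| `Rp`, `hNa` | cycles s⁻¹, mM | 0, 8 | pump rate (capacity) and Na⁺ half-occupation |
| `x`, `y` | ions/cycle | 3, 2 | pump stoichiometry (3:3 electroneutral, 3:0 pure Na⁺ pump, …) |
| `Rnkc`, `Rkc` | cycles s⁻¹ | 0 | cotransporter rates |
| `z` | – | −1 | mean valence of the impermeant anion; `z ≠ −1` creates osmolarity-charge asymmetry |
| `tau` | s | 1 | water-permeability time constant; `≤ st` instant, `> 10⁸` watertight |
| `st` | s | 10⁻³ | time step (10⁻⁴ s for voltage transients) |

The *rate* of a transporter is a fixed capacity; its *activity* is the
realised cycles/s and is concentration dependent.  Sweep tables therefore
report both, since published curves are usually plotted against activity.

Concentrations are mM at every user-facing interface; inside the stepper
they are carried in mol/L so the amount-to-concentration conversion
`dX/(vol·L)` needs no hidden factor of 1000.

## Steady states, sweeps, and rate finding

`run_to_steady_state()` integrates until the net flux of each ion,
expressed as a concentration rate, stays below `steady_tol` (default
10⁻⁹ mM/s) for ten consecutive checks spaced 200 steps apart.  This
tolerance is tight enough to reproduce the Donnan product to ten
significant digits after a 90-minute relaxation, yet is reached within
seconds of simulated time in pump-leak settings.  Because the detector
requires a sustained hold, an already-balanced state reports an elapsed
time of a couple of simulated seconds rather than exactly zero.
A monotonic volume increase past ten times the initial volume is reported
as non-convergent "unbounded swelling" — the genuine fate of a
water-permeable pure Donnan system — rather than looping forever.

`sweep_steady_states()` computes one steady state per parameter value and
flags non-convergent points without failing.  `find_rate_for_condition()`
locates the transporter rate at which a scalar predicate of the steady
state crosses zero, by Brent root-finding on the log₁₀ rate after
verifying the bracket straddles; this recovers, for example, the pump rate
at which the cation gradients are exactly reversed, a point published
curves give only as an activity.

## Numerical choices

* **Fixed-step explicit integration** is deliberate: the discrete cycle
  *is* the model.  Steady states are fixed points of the map and therefore
  independent of `st`; we verify that halving `st` changes 20-minute
  trajectory values by far less than 0.1%.  The default `st` of 1 ms is
  safe for total conductances up to ≈3×10¹⁰ ions s⁻¹ V⁻¹ (membrane time
  constant 2.5 ms); scenarios that open 10¹¹ of Cl⁻ conductance drop to
  0.1 ms, keeping the voltage update well inside the stability region.
* **Volume relaxation is exactly exponential** for a single osmotic
  disturbance at constant composition: the update `vol ← vol·chV` is the
  Euler discretisation of `dvol/dt = −(vol − vol_eq)/tau`, and the
  trajectory matches the closed form
  `vol(t) = vol₁ + (vol₂ − vol₁)(1 − e^(−t/τ))` to ≈10⁻⁵ relative.
* **Clamping**: `VoR = 1/tau` is clamped to `1/st` when `tau < st`
  (instant water, `chV = osV`, internal osmolarity equals the bath after
  every step to 10⁻¹² relative) and to 0 when `tau > 10⁸ s` (no water
  flux).  A non-positive `chV` aborts with an explicit osmotic-collapse
  error instead of producing a negative volume.
* **Degenerate inputs**: a conductance or rate of exactly zero silences
  its pathway without evaluating logarithms, so fully impermeant ions (even
  at zero concentration) are representable.  If a step would drive a
  permeant ion's concentration through a 10⁻¹² mol/L floor, the step is
  re-done as two half steps (recursively, to a depth limit), which protects
  extreme sweeps without altering ordinary trajectories.
* **Tie-breaks in the charge ledger**: `Em` and the cumulative transferred
  charge are accumulated separately and agree to 10⁻¹² relative at every
  snapshot — this identity, along with impermeant-amount conservation, is
  tested property-style across scenario families.
* The undefined pump-mediated Cl⁻ flux term that appears in one published
  statement of the accumulation step is taken as identically zero: the
  Na⁺/K⁺-ATPase transports no Cl⁻.
* The asymmetry-coefficient resting potential is implemented as
  `Em = −(RT/F)·ln(2ka/(ka+1))`: a cell holding excess cations
  (`ka > 1`) rests hyperpolarised, which is the sign consistent with
  `Em = E_Na = E_K` at equilibrium (e.g. −9.5 mV at `ka = 2.5`).
* Physical constants are carried at the precision used throughout the
  domain literature for this model (e = 1.6×10⁻¹⁹ C, L = 6.02×10²³ mol⁻¹,
  F = 96485 C mol⁻¹); consequently `e·L` matches `F` to ≈2×10⁻³, not to
  machine precision, and the decade potential is 61.48 mV at 309.85 K.

## Scenarios

The registry (`list_scenarios()`) encodes the classic numerical
experiments as ready-made initial conditions: pure Donnan relaxation with
a watertight membrane, the same opening with osmotically obliged water
(unbounded swelling), Double Donnan stabilised by 135 mM external neutral
osmolyte, a Na⁺-impermeable K⁺/Cl⁻ Double Donnan, electroneutral and
electrogenic pump transients and sweeps, Cl⁻-conductance openings on a
pump-leak resting state, NKCC/KCC rate sweeps, four osmolyte-buildup
protocols and a pump-free asymmetry sweep.  Two concentration
configurations recur: a *symmetric* one (`z = −1`, no neutral osmolytes)
in which charge and osmolarity bookkeeping coincide, and an *asymmetric*
one (`z = −1.5` with 6 mM external neutral osmolyte, `ka = 1.5`) whose
passive cation equilibrium rests at −4.87 mV.

Scenario initial states are the published legend values, which are rounded
to 0.1 mM; where a legend states a pump *activity*, the rate is recovered
through the occupation factor at the legend's [Na⁺]ᵢ.  Because of that
rounding, some "resting" starts carry millivolt-scale residual imbalance
that the first simulated seconds relax away; steady-state comparisons are
therefore made against converged states, not against the raw legend
values.

## What the scenarios do and do not emulate

The scenario suite exercises every transport mechanism of the model under
the conditions the model was designed for: an isolated cell in an infinite
bath, voltage-insensitive conductances, fixed membrane area and
capacitance, no bicarbonate/pH coupling, no extracellular-space dynamics
and no glia.  Passing tests demonstrate internal consistency of the
mass/charge/volume bookkeeping and agreement with the analytic equilibrium
theory — they do not certify quantitative accuracy for any real neuron,
where voltage-gated channels, bicarbonate transport and a finite
extracellular compartment all matter.

## Problem sizes used in the test-suite

Unit and property tests integrate seconds-to-minutes of simulated time at
1 ms steps; the deepest checks are a 20-minute Donnan relaxation at two
step sizes (discretisation convergence), a 90-minute relaxation for the
product rule, steady-state sweeps of 13 pump rates, and five
stoichiometry tunings by rate bisection.  The whole suite integrates a few
tens of millions of scalar steps, which the compiled core completes in
well under a minute.

## Known limitations

* Cotransporter activities are unbounded in the log driving force; extreme
  rates (≥10¹² cycles/s) are numerically fine but physiologically
  meaningless beyond demonstrating the thermodynamic Cl⁻ limits.
* The `z = −3` and buildup scenarios assume the accompanying-cation rule
  for electroneutral anion addition; other accompaniment choices (e.g. H⁺
  with pH chemistry) are out of scope.
* Surface area and capacitance are fixed, so volume excursions beyond the
  cube-to-sphere reserve (≈+40%) should be read qualitatively.
* The published figure set includes states produced by unpublished
  preparatory calculations; where a printed legend is internally
  inconsistent at the 0.1 mM level, converged model values can deviate
  from printed readouts by of order 1 mV or 0.1 mM (the package's own
  converged values are the reproducible reference).
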