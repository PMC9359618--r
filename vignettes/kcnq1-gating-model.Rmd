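---
title: "A 12-state allosteric gating model of KCNQ1 and its drug-perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 12-state allosteric gating model of KCNQ1 and its drug-perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

KCNQ1 gating is represented as a continuous-time Markov chain over 12 states:
six voltage-sensor configurations — `C0..C4` counting how many of the four
S4 helices sit in the intermediate state, plus `CA` for the concerted,
fully-activated configuration — duplicated for a closed and an open pore
(`O0..O4`, `OA`). Voltage-sensor activation is a two-step process: four
independent resting→intermediate transitions, then one concerted
intermediate→activated step of all four S4s. The pore can open from every
configuration; it does not have to wait for full sensor activation. Each S4
in the intermediate state multiplies the pore opening rate by an allosteric
factor `L >= 1`, and the concerted configuration contributes a further factor
`D >= 1`. This is the MWC-style allosteric architecture in which sensor
activation biases, rather than gates, pore opening.

Rates carry single-barrier (Eyring) voltage dependence,
`k(V) = k0 exp(±z V / VT)` with `VT = 25.4` mV (thermal voltage scale at the
oocyte recording temperature, ~22 °C). Statistical factors count the
available sensors: `Cj -> Cj+1` proceeds at `(4-j) alpha(V)`, `Cj+1 -> Cj`
at `(j+1) beta(V)`.

**Thermodynamic consistency.** Because opening is allowed from every
configuration, the scheme contains cycles. The allosteric bias must therefore
appear in the voltage-sensor rates of the open tier: forward rates are
multiplied by `L^x` and backward rates by `L^(x-1)` (`D` analogously at the
concerted step), where `x = x_split` in `[0, 1]`. Any split keeps every
cycle's clockwise and counter-clockwise rate products equal;
`thermodynamic_consistency()` verifies all five cycles to 1e-10 and is
exercised on randomly drawn parameter sets in the test suite. `x_split`
controls where the retrograde coupling acts: `x = 0` puts all of it into
slowed backward sensor rates while the pore is open, `x = 1` into sped
forward rates.

**Observables.** Current is ohmic, `I = Gmax P_open (V - E_K)` with
`E_K = -105` mV (ND96 bath, 2 mM external K⁺). The fluorescence signal
mimics a fluorophore at the S3–S4 linker reporting S4 displacement: each
intermediate S4 contributes `w_I / 4`, the concerted configuration `w_A`,
independent of the pore. For display, traces can be min–max normalized; for
paired control/drug figures the control trace's scale is reused so
drug-induced amplitude changes stay visible (tail-fit time constants are
normalization-invariant, so all quantitative results use raw fluorescence).

## Simulation

Protocols are piecewise-constant voltage programs. Within a segment the
generator `Q(V)` is constant, so occupancies propagate exactly by one matrix
exponential per sample step, `p(t + dt) = p(t) expm(Q dt)` — no ODE-solver
tolerance enters any result, halving the sample interval leaves shared time
points unchanged to 1e-8, and occupancy is conserved to better than 1e-9
over a 4-s protocol (both are tested invariants). The initial condition is
the steady state at the holding voltage. Default sample interval: 1 ms.

The standard protocols mirror two-electrode voltage clamp / VCF practice on
Xenopus oocytes: hold −80 mV; a 0.2-s recorded baseline segment (used later
for noise estimation); +20 mV for 2 s; −120 mV for 2 s. The activation
family steps from −140 to +80 mV in 20-mV increments (2 s) before the
−120 mV tail.

## Measurements

* **Tail time constants.** Single-exponential least squares
  `y = A exp(-(t - t0)/tau) + C` over a window starting 10 ms after the
  repolarizing step (skipping the instantaneous ohmic jump; the paper-style
  convention does not state a window, so one convention is applied uniformly
  to control and drug). Fits run Levenberg–Marquardt (`minpack.lm::nls.lm`)
  from a small deterministic grid of starting values; on noiseless members of
  the model class the residual RMS reaches 1e-10, which the tests assert.
  A segment whose leading and trailing levels differ by less than five times
  the noise of that difference is rejected as non-decaying. Half-decay times
  (`half_decay_time()`) are provided for the cases where experimental
  practice falls back to t½.
* **Isochronal G(V)/F(V).** Current and fluorescence at the final sample of
  each 2-s test pulse, normalized to the family maximum, with no
  driving-force correction — matching how activation curves are measured
  from such recordings — then fitted with a four-parameter Boltzmann
  (minimum free, because simulated F(V) has a nonzero floor). On noisy
  pipeline data the isochronal readout averages the final 10 ms, emulating
  an analysis cursor.
* **Drug-effect summary.** Six metrics: percent change of end-pulse current
  at +20 mV, of the current and fluorescence tail τ at −120 mV, of the
  fluorescence activation τ at +20 mV, and the G(V)/F(V) midpoint shifts.

## Baseline parameters and their calibration

The defaults (`default_params()`, mirrored in
`inst/extdata/default_params.cfg`) are not taken from any printed table; they
were derived once by calibrating the free constants against the behaviour the
model must reproduce, and then frozen:

* slow sigmoidal current activation at +20 mV and a mono-exponential tail at
  −120 mV (control tail τ ≈ 47 ms for current, ≈ 86 ms for fluorescence);
* F(V) hyperpolarized relative to G(V) (midpoints ≈ −28 vs ≈ −2 mV);
* under the voltage-sensor perturbation (backward rate ×1/3.4, conductance
  ×1.24): fluorescence tail slowing ≈ +225%, current ≈ +135%, both
  activation curves shifted negative with the F(V) shift larger;
* under a common pore open/close slowing calibrated to +363% current tail
  slowing: fluorescence tail slowing ≈ +41%, unchanged fluorescence
  activation kinetics (<5%), no appreciable G(V)/F(V) shifts (<1 mV).

Three structural lessons from that calibration are worth recording. First,
the 2-s isochronal readout only sits near equilibrium if the first VSD step
is kinetically fast at mid voltages; a shallow backward charge
(`z_beta = 0.55`) keeps the −120 mV tail slow while mid-range equilibration
takes ~0.3 s. Second, the G(V) midpoint responds to a shift of the first
VSD step's equilibrium only when that step's midpoint lies within ~25 mV of
the G(V) transition; `alpha0` sets this proximity. Third, the pore-closing
latency `1/kc0` is the one component of the current tail that does not scale
with `beta`, so `kc0` controls how much less the current tail slows than the
fluorescence tail under a pure sensor perturbation. `kc0 = 36 /s` is a
compromise between that ratio at the ×1/3.4 perturbation and the stronger
perturbations used by the synthetic presets.

| field | meaning | unit | default |
|---|---|---|---|
| `alpha0`, `z_alpha` | forward independent S4 step | 1/s, e | 7.9, 1.55 |
| `beta0`, `z_beta` | backward independent S4 step (main deactivation) | 1/s, e | 1.0, 0.55 |
| `theta0`, `z_theta` | concerted forward step | 1/s, e | 6.0, 0.30 |
| `eta0`, `z_eta` | concerted return step | 1/s, e | 0.0314, 2.0 |
| `ko0`, `kc0` | base pore opening / closing | 1/s | 0.206, 36 |
| `L`, `D` | allosteric factors (per intermediate S4; concerted) | — | 3, 6 |
| `x_split` | open-tier detailed-balance split | — | 0.1 |
| `Gmax`, `E_K` | conductance scale, reversal | a.u., mV | 1, −105 |
| `w_I`, `w_A` | fluorescence weights | — | 0.8, 1 |
| `VT` | rate voltage scale | mV | 25.4 |

`x_split = 0.1` places the retrograde coupling almost entirely in slowed
backward sensor rates of the open tier; larger values speed the open-tier
forward rates instead, which measurably perturbs fluorescence *activation*
kinetics under pore slowing — an effect the data say is absent.

## Drug perturbations

A perturbation is a named set of multiplicative factors:
`s_pore_open` (on `ko0`), `s_pore_close` (on `kc0`), `s_vsd_deact` (on
`beta0` — the backward rate of the *independent* S4 step, applied in both
tiers through the split rule), and `s_conductance` (on `Gmax`). Scaling base
rates preserves detailed balance automatically.

Two interpretive choices are fixed here (and echoed in the CLI log). A
"240% decrease" of a rate is read as the rate scaled by `1/(1 + 2.4) = 1/3.4`
— equivalently, its time constant increased by 240% — which is the reading
consistent with the resulting ≈ +224% fluorescence-tail prediction. The
"main voltage sensor transition" is the independent resting↔intermediate
step (`beta`), not the concerted return (`eta`): fluorescence deactivation
tracks the first-step return in a two-step scheme. Both remain ordinary
arguments, so the alternatives are selectable.

`calibrate_pore_slowing()` finds the common pore open/close factor producing
a requested current-tail slowing by bracketing and bisection in `log f`
(the map is monotone; tolerance 0.5% of the target).

## Synthetic paired experiments

`generate_experiment()` emulates a paired control/drug VCF experiment on
pseudo-wild-type KCNQ1: per cell, the six base rates receive shared
log-normal jitter (CV 0.10), and each *recording* receives an independent
log-normal amplitude factor (CV 0.12). The amplitude jitter is deliberately
per-recording rather than per-cell: a shared cell amplitude cancels exactly
in paired percent changes, whereas recording-to-recording rundown and drift
are what give the published ΔI statistics their ±8% SEM at n = 5. Additive
Gaussian noise (2% of the control peak current; 2% of the control
fluorescence range) is applied to both channels, with the control trace's
scales shared by the paired drug trace. All randomness derives from one
integer seed; a manifest stores every cell's true parameters at full double
precision, so re-simulating from the manifest reproduces the stored
noiseless traces bit-for-bit (a tested invariant).

The shipped presets' perturbation factors were calibrated once
(`calibrate_preset_factors()`) so the *noiseless* analysis pipeline lands on
the experimental percent-change statistics each preset emulates, and then
frozen. The presets emulate those statistics; they do not claim to be the
drugs' mechanisms. Two calibration facts make this explicit. For
`ml277_pswt`, pure pore slowing reproduces the current-tail statistic but
not the observed +88% fluorescence-tail slowing, so the preset carries a
mild sensor factor (0.663) alongside the pore factors. For `rl3_pswt`,
matching the pair (+199% current, +335% fluorescence) requires *asymmetric*
pore factors (opening ×2, closing ×8): faster closing is the only lever that
speeds the current tail without touching the fluorescence tail. Within the
mechanistic reading of the drugs these factors are emulation devices, not
inferred drug actions.

What the generator does **not** emulate: leak and capacitive transients,
series resistance, fluorophore bleaching and drift, endogenous-current
contamination, La³⁺ block, inactivation. Tests passing on this generator
therefore demonstrate correctness of the pipeline under its stated noise
model, not robustness to those artifacts.

## Recovering perturbations from data

`recover_perturbation()` fits selected multipliers per cell by weighted
least squares between the observed drug two-pulse trace and simulations from
the cell's manifest baseline, weighting the current and fluorescence
channels by inverse noise variance estimated from the pre-pulse baseline
segment. Optimization runs on log-multipliers (bounds 1/1000..1000,
L-BFGS-B) from a fixed set of multi-starts; the aggregate is the geometric
mean across cells. Because the control recording's amplitude factor is
folded into the baseline, the per-cell conductance truth is
`s_conductance x g_drug / g_ctrl`; the manifest makes this truth available
for validation. With the default noise model and five cells, the named
sensor and conductance factors are recovered within a few percent.

`model_selection()` fits the pore mechanism (one common pore factor +
conductance) and the sensor mechanism (sensor factor + conductance) with
multipliers shared across cells and ranks them by
`AICc = chi^2 + 2k + 2k(k+1)/(n-k-1)` computed from the Gaussian residuals;
differences below 2 are reported as indistinguishable, which is what an
identity-perturbation dataset produces.

## Numerical choices

* Matrix exponentials via `Matrix::expm` on the 12×12 generator; one
  exponential per protocol segment, then per-sample vector–matrix products.
* Steady states by least squares on the augmented system `[Q^T; 1]`, with a
  condition-number guard (error above 1e12).
* Internal occupancy drift beyond 1e-6 raises an internal error rather than
  renormalizing silently.
* Curve fits: `minpack.lm::nls.lm` multi-start as described; the
  lowest-deviance candidate wins ties deterministically by grid order.
* Text formats everywhere (12 significant digits for traces and configs;
  17 for the manifest truth), so every artifact diffs and checksums cleanly.

Problem sizes used by the shipped tests were chosen to probe each claim at
the smallest informative scale: replicate studies use 3–8 cells at 5–10 ms
sampling, the mechanism-selection study uses 20 five-cell replicates, and
the quantitative drug-signature checks run at the full 1-ms resolution.

## Known limitations

* No inactivated states: the scheme cannot reproduce inactivation-linked
  phenomena, and "half-inactivation" readouts are out of scope.
* No KCNE1-containing (I_Ks) model; the drugs' KCNE1-dependence is outside
  the model's reach.
* Single-channel stochastics, temperature dependence beyond `VT`, and
  recording artifacts (above) are not modelled.
* The baseline is a calibrated representative of psWT KCNQ1 behaviour, not a
  fit to any specific cell; absolute time constants and midpoints should be
  read as typical, with the percent-change predictions being the quantities
  the calibration pins down.
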