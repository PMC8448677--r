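---
title: "Determining k_on, k_off and K_i from pre-equilibrium inhibition titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining k_on, k_off and K_i from pre-equilibrium inhibition titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preqkin)
```

## The measurement principle

A titration of a reversible inhibitor read out *at equilibrium* determines
one number, K_i (for tight binders via the Morrison quadratic model,
because free and total inhibitor differ when E_0 ~ K_i). The same
titration read out at several incubation times *before* equilibrium
determines three: the shape of each partial-occupancy curve and how it
deepens with time encode k_on and k_off separately, and
K_i = k_off/k_on follows. This also removes the practical obligation to
wait for equilibration, which for slowly dissociating inhibitors can
exceed the stability window of the reagents.

`preqkin` models the occupancy of E + I ⇌ EI mixed at t = 0 with the
exact integrated solution of

$$\frac{d[\mathrm{EI}]}{dt} = k_{on}(E_0-[\mathrm{EI}])(I_0-[\mathrm{EI}]) - k_{off}[\mathrm{EI}],$$

and the observable as the free-enzyme fraction,
$v_i = v_0\,(E_0-[\mathrm{EI}]_t)/E_0$. Assumptions worth stating:

* **1:1 single-step binding.** No induced-fit/two-step mechanisms; a
  mechanism with a fast pre-equilibrium followed by isomerisation will
  fit with effective constants.
* **Initial rates are proportional to free enzyme.** Valid when the
  readout window is short relative to binding kinetics and substrate
  consumption (the 10% hydrolysis guard below).
* **No enzyme inactivation or inhibitor depletion by degradation** over
  the incubation series.
* **Apparent vs true constants.** Everything fitted is *apparent*. For a
  competitive substrate, $K_{i,app} = K_i(1+S/K_m)$,
  $k_{on,app} = k_{on}/(1+S/K_m)$, $k_{off,app} = k_{off}$. The package
  keeps the correction **off by default** (S/K_m treated as 0, the usual
  regime $S \ll K_m$ for fluorogenic protease substrates) and applies it
  only when both `S` and `K_m` are supplied — `apparent_from_true()` /
  `true_from_apparent()` are exact inverses.

## Parameters that matter

| quantity | unit | default | why |
|---|---|---|---|
| `E_0` | mol/L | user-supplied, fixed in the fit | known from the assay; treating it as shared-adjustable is supported (`E_0_mode = "shared-adjustable"`) but trades precision for robustness to titration error |
| `timepoints` | s | simulator: 300, 900, 2700, 7200 | spans clearly pre-equilibrium to near-equilibrated curves for nM-potency binders at nM enzyme; a family that is *all* equilibrated loses k_on/k_off identifiability (flagged, see below) |
| dilution grid | mol/L | 11-point twofold from 16 nM + 0 control | brackets E_0 so the curves traverse the stoichiometric regime where tight-binding information lives |
| `noise_sd` | fraction of v_0 | 0.02 | additive Gaussian noise on rates; matches the equal-weighting least-squares objective |
| `v_0_mode` | – | `"shared"` | one uninhibited rate for all curves; `"per-timepoint"` absorbs between-plate drift |
| rate-constant bounds | – | k_on ∈ [1e2, 1e10] M⁻¹s⁻¹, k_off ∈ [1e-8, 1e2] s⁻¹ | generous physical limits; optimisation is on log10 scale |
| QC: linearity | – | r² ≥ 0.98 over the first 60 s | our own bar for "linear trace"; failing wells are excluded with a logged count, never silently |
| QC: hydrolysis | – | fraction ≤ 0.10 (boundary passes) | initial-rate validity; indeterminate (not failing) when the signal-per-product calibration is missing |

## What the simulator emulates — and what it does not

`simulate_titration()` reproduces the *structure* of a plate-based
pre-equilibrium protease assay: one enzyme concentration, a serial
dilution plus mandatory no-inhibitor control, several incubation times,
one measurement per well, additive rate noise from a mandatory seed (no
silent global RNG). `simulate_progress_trace()` generates linear raw
traces so the initial-rate extractor can be validated end to end.

It deliberately does **not** emulate: substrate-depletion curvature,
inner-filter effects, enzyme inactivation over long incubations, pipetting
(serial-dilution) error, or plate-position effects. A green round-trip
test therefore establishes that the estimator inverts its own generative
model — correctness of the numerics and the fitting machinery — not that
every laboratory systematic is handled. The replicate-level noise model
(2% of v_0) is our choice: real experiments report only the
inter-experiment variability of the fitted parameters, not a rate-level
noise law, and a fraction-of-v_0 Gaussian is the simplest model consistent
with unweighted least squares.

## Numerical choices

**A cancellation-free closed form.** The textbook expression for
$[\mathrm{EI}]_t$ is 0/0 at t = 0 and loses digits when
$E_0 \approx I_0$ with small $k_{off}$. We evaluate the algebraically
identical form

$$[\mathrm{EI}]_t = \frac{(a-b)\,(1-e^{-bt})}{2k_{on}\left[(1-e^{-bt}) + \tfrac{2b}{a+b}e^{-bt}\right]},$$

whose terms are all nonnegative (no cancellation), uses `expm1` for small
$bt$, contains only $e^{-bt}$ (no overflow at any $bt$), and tends
smoothly to the degenerate-limit series $a^2t/(2k_{on}(2+at))$ as
$b \to 0$ (an exact branch handles $b = 0$, and $t = 0$ / $I_0 = 0$
return 0 exactly). The radicand of $b$ is computed as
$(k_{on}(\sqrt{E_0}-\sqrt{I_0})^2 + k_{off})(a + 2k_{on}\sqrt{E_0I_0})$,
which is exactly nonnegative term by term.

**An independent oracle.** `ei_ode_oracle()` integrates the rate law
directly with an adaptive Cash–Karp RK45 stepper (default rtol 1e-8) and
never touches the closed form; the test suite sweeps 100 random parameter
sets over 4 decades of concentration and rate constants and requires
agreement within 1e-6 of min(E_0, I_0). Because explicit steppers are
stability-limited after the transient, integration stops after 60
relaxation times of the fixed point (computed from the rate law's own
Jacobian), where the remaining drift is below double precision.

**Fitting.** Unweighted least squares over all curves jointly; k_on and
k_off (and E_0 if freed) on the log10 scale for positivity and scale
invariance; bounded quasi-Newton (`nlminb`) from a default 4×4 log-spaced
multistart grid (k_on 1e4–1e7, k_off 1e-5–1e-2) because near-equilibrated
families make the objective flat-to-multimodal; RSS ties (relative
difference < 1e-12) break toward smaller k_off, the conservative
(longer-residence-time) claim. v_0 starts at the mean of the no-inhibitor
controls. Standard errors are asymptotic, from the numerical Jacobian at
the optimum; K_i's SE uses the full covariance of (log k_on, log k_off).
No bootstrap by default.

**Identifiability.** At equilibrium the model depends on k_off/k_on only.
The fit reports the column-scaled singular-value ratio of its Jacobian;
below 1e-3 (empirically the scale of $e^{-bt_{\min}}$ once every curve is
within ~0.1% of equilibrium, and orders of magnitude below the ~0.5 of
informative designs) it flags that only K_i is determined. A
single-timepoint dataset fits with a warning; a curve showing < 2%
inhibition depth returns a "no-inhibition" diagnostic instead of a
pseudo-estimate of K_i,app.

## Design choices where the design was open

* **Units:** SI (mol/L, s) everywhere internally; human-facing reports
  and CSVs convert (nM, M⁻¹s⁻¹, s⁻¹) and always declare units — the two
  layers never mix, which kills the classic nM/M fitting bug.
* **File contracts:** tidy long-format CSV (one rate per row:
  `time_s, inhibitor_conc, rate[, replicate, qc_pass]`) rather than
  plate-shaped matrices; traces are per-well CSVs
  (`time_s, fluorescence_au`) tied to doses by a small manifest CSV,
  since proprietary plate layouts are out of scope.
* **Config:** one JSON file per run (`run_pipeline()`), flags overriding
  keys in the CLI wrapper; JSON because it is structured, diff-able and
  needs no extra dependency.
* **Blank handling:** an optional no-enzyme blank trace is subtracted
  pointwise when supplied; no automatic blank inference.
* **Calibration:** signal-per-product is user-supplied; without it the
  hydrolysis guard reports "unknown" rather than guessing a fluorophore
  standard curve.

## Known limitations

* Single-step 1:1 binding only; no mixed/uncompetitive correction
  formulas (only the competitive case has a closed form here).
* Initial rates only — progress curves are never fitted directly, so
  information in trace curvature is unused by design.
* Asymptotic SEs understate uncertainty when the optimum is near a bound
  or the Jacobian is ill-conditioned (the flag, not the SE, is the signal
  to trust there).
* For the slowest-dissociating inhibitors, k_off precision is intrinsically
  limited by how much equilibration the longest timepoint captures;
  widening the timepoint span is the remedy, not more replicates per
  point.
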