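# preqkin

Binding kinetics of enzyme inhibitors from **pre-equilibrium titration
curves**.

## The problem

The potency of a reversible enzyme inhibitor is usually summarised by the
equilibrium inhibition constant K_i, but K_i says nothing about *how fast*
the inhibitor engages and releases its target — the rate constants k_on and
k_off, and the residence time 1/k_off, which increasingly drive lead
selection in drug discovery. For potent ("tight-binding") inhibitors two
extra complications arise: the assay must run at E_0 ~ K_i, so free and
total inhibitor differ and the simplified hyperbolic models break down; and
slow equilibration means a conventional endpoint titration may be read out
*before* the system has equilibrated, silently biasing K_i.

`preqkin` implements an analysis that turns the second problem into the
measurement principle: inhibition curves (initial rate of substrate
hydrolysis vs inhibitor dose) are recorded at **several incubation times
before equilibrium** and fitted **globally** with the exact integrated 1:1
binding model, yielding k_on, k_off and K_i = k_off/k_on from a single
experiment. The package targets plate-reader protease assays (the
reference system is human plasma kallikrein inhibited by bicyclic
peptides) but the model is generic 1:1 binding.

## The model

For E + I ⇌ EI with total concentrations E_0, I_0 and rate constants
k_on, k_off, the complex concentration obeys

    d[EI]/dt = k_on (E_0 − [EI]) (I_0 − [EI]) − k_off [EI],   [EI]_0 = 0,

whose closed-form solution is

    [EI]_t = (a(1−c) − b(1+c)) / (2 k_on (1−c)),
    a = k_on (E_0 + I_0) + k_off,
    b = sqrt(a² − 4 k_on² E_0 I_0),
    c = ((a−b)/(a+b)) e^(−bt).

The measured rate is the free-enzyme fraction, v_i = v_0 (E_0 − [EI]_t)/E_0.
At t → ∞ this reduces to the classical Morrison tight-binding curve with
K_i,app = k_off/k_on; for competitive inhibition
K_i,app = K_i (1 + [S]/K_m), k_on,app = k_on/(1 + [S]/K_m),
k_off,app = k_off.

## Worked example

Simulate a four-timepoint titration of a 0.055 nM inhibitor
(k_on = 3.5×10⁶ M⁻¹s⁻¹, k_off = 1.92×10⁻⁴ s⁻¹) at 1 nM enzyme with 2%
rate noise, then fit all four curves globally:

```r
library(preqkin)
p    <- binding_parameters(k_on = 3.5e6, k_off = 1.92e-4)
cond <- assay_conditions(E_0 = 1e-9, timepoints = c(300, 900, 2700, 7200))
d    <- simulate_titration(simulation_spec(p, cond, noise_sd = 0.02, seed = 11))
fit_preequilibrium(d)
#> Global pre-equilibrium fit
#>   k_on  = 3.46e+06 M^-1 s^-1 (SE 1.4e+05, CV 4.2%)
#>   k_off = 0.000151 s^-1 (SE 2.1e-05, CV 13.9%)
#>   K_i   = 0.0438 nM (SE 0.0054 nM)
#>   E_0   = 1 nM (fixed)
#>   RSS = 0.01327 over 48 points; convergence 1
```

The shared k_on and k_off are recovered with single-digit / low-double-digit
percent uncertainty from one noisy synthetic experiment; K_i is their ratio.

The converse diagnosis — how wrong a conventional equilibrium analysis is
on a not-quite-equilibrated curve — is one call:

```r
rep <- equilibration_bias_report(binding_parameters(1.37e6, 2.99e-4),
                                 E_0 = 2e-9, t = 900)
#> fitted 0.343 nM vs true 0.218 nM: bias ratio 1.57
```

i.e. a 15-minute incubation of this slowly equilibrating inhibitor inflates
the fitted K_i by ~60%.

Other entry points: `fit_initial_rate()` / `hydrolysis_fraction()` extract
QC-guarded initial rates from raw fluorescence traces; `fit_equilibrium()`
is the Morrison endpoint fit; `run_pipeline()` (and the thin CLI at
`inst/cli/preqkin.R`) drives simulate → rates → fit → report from a JSON
config, writing `fit_report.csv`, `fit_report.txt` and
`kon_koff_scatter.csv` in conventional units (nM, M⁻¹s⁻¹, s⁻¹).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the apparent K_i
obtained by fitting the Morrison equilibrium model to a noiseless titration
curve of the reference inhibitor (k_on = 1.37×10⁶ M⁻¹s⁻¹,
k_off = 2.99×10⁻⁴ s⁻¹, E_0 = 2 nM, 11-point twofold dilution from 16 nM
plus control) generated (t1) after a 15-minute pre-equilibrium incubation
and (t2) at full equilibration, and writes both values (nM) as JSON.
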