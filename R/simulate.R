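# Synthetic pre-equilibrium titration data with the structure of a
# plate-based protease inhibition assay: a serial dilution of inhibitor
# plus a no-inhibitor control, pre-incubated with enzyme for several
# times before substrate addition, read out as initial rates.

#' Serial dilution concentration series
#'
#' `n` concentrations stepping down from `top_I0` by `factor`, followed by
#' a terminal 0 entry (the no-inhibitor control), as pipetted in a serial
#' dilution across a plate row.
#'
#' @param top_I0 Highest inhibitor concentration (mol/L), > 0.
#' @param factor Dilution factor between adjacent wells, > 1 (default 2).
#' @param n Number of nonzero concentrations, >= 1.
#' @return Numeric vector of length `n + 1`, strictly decreasing, ending
#'   in 0.
#' @examples
#' dilution_series(8e-9, 2, 4)   # 8, 4, 2, 1 nM and the 0 control
#' @export
dilution_series <- function(top_I0, factor = 2, n) {
  stopifnot(is.numeric(top_I0), length(top_I0) == 1L,
            is.numeric(factor), length(factor) == 1L,
            is.numeric(n), length(n) == 1L)
  if (!is.finite(top_I0) || top_I0 <= 0) stop("`top_I0` must be > 0 (mol/L)")
  if (!is.finite(factor) || factor <= 1) stop("`factor` must be > 1")
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer")
  c(top_I0 / factor^(0:(n - 1)), 0)
}

#' Specification of a synthetic titration experiment
#'
#' Collects everything needed to generate a [simulate_titration()] dataset.
#' Defaults mirror a typical tight-binding protease assay: an 11-point
#' twofold dilution from 16 nM bracketing a ~1 nM enzyme concentration,
#' incubation times from 5 min to 2 h so that both clearly pre-equilibrium
#' and near-equilibrated curves are present, and additive Gaussian noise
#' on rates of 2% of the uninhibited rate.
#'
#' @param params [binding_parameters()] of the simulated inhibitor.
#' @param conditions [assay_conditions()]; its `timepoints` are the
#'   incubation times simulated.
#' @param top_I0 Highest inhibitor concentration (mol/L).
#' @param dilution_factor Serial dilution factor, > 1.
#' @param n_dilutions Number of nonzero concentrations, >= 4.
#' @param v_0_true Uninhibited initial rate (signal/s).
#' @param noise_sd Standard deviation of additive rate noise, as a
#'   fraction of `v_0_true` (default 0.02); 0 gives exact model values.
#' @param seed Integer RNG seed; mandatory so every dataset is
#'   reproducible.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(params, conditions, top_I0 = 16e-9,
                            dilution_factor = 2, n_dilutions = 11,
                            v_0_true = 1, noise_sd = 0.02, seed) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(conditions, "assay_conditions"))
  if (missing(seed)) stop("`seed` is mandatory for a simulation spec")
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("`seed` must be a single integer")
  if (!is.finite(top_I0) || top_I0 <= 0) stop("`top_I0` must be > 0")
  if (!is.finite(dilution_factor) || dilution_factor <= 1)
    stop("`dilution_factor` must be > 1")
  if (n_dilutions < 4) stop("`n_dilutions` must be >= 4")
  if (!is.finite(v_0_true) || v_0_true <= 0) stop("`v_0_true` must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(params = params, conditions = conditions, top_I0 = top_I0,
                 dilution_factor = dilution_factor,
                 n_dilutions = as.integer(n_dilutions),
                 v_0_true = v_0_true, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# run code with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a pre-equilibrium titration dataset
#'
#' One initial rate per (incubation timepoint x dilution entry), computed
#' with the integrated 1:1 binding model via [residual_rate_preeq()] and
#' perturbed by additive Gaussian noise `Normal(0, noise_sd * v_0_true)`
#' drawn from a private generator seeded by `spec$seed`.  With
#' `noise_sd = 0` the rates equal the model predictions exactly; the same
#' spec always yields the identical dataset.
#'
#' @param spec A [simulation_spec()].
#' @return A [titration_dataset()].
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  conc <- dilution_series(spec$top_I0, spec$dilution_factor, spec$n_dilutions)
  tps <- spec$conditions$timepoints
  grid <- expand.grid(I0 = conc, time_s = tps,
                      KEEP.OUT.ATTRS = FALSE)[, c("time_s", "I0")]
  mu <- residual_rate_preeq(spec$v_0_true, grid$time_s,
                            spec$conditions$E_0, grid$I0, spec$params)
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed,
               stats::rnorm(nrow(grid), 0, spec$noise_sd * spec$v_0_true))
  else 0
  records <- data.frame(time_s = grid$time_s, I0 = grid$I0, rate = mu + noise)
  titration_dataset(records, spec$conditions,
                    provenance = sprintf(
                      "simulated: k_on=%.6g, k_off=%.6g, E_0=%.6g, v_0=%.6g, noise_sd=%.3g, seed=%d",
                      spec$params$k_on, spec$params$k_off,
                      spec$conditions$E_0, spec$v_0_true, spec$noise_sd,
                      spec$seed))
}

#' Simulate a raw fluorescence progress trace
#'
#' A linear product-formation trace, `signal(t) = baseline + v_true * t`
#' plus i.i.d. Gaussian signal noise -- the idealised early portion of a
#' plate-reader well in which substrate depletion is negligible.  Because
#' the trace is linear by construction, [fit_initial_rate()] must recover
#' `v_true` (exactly at zero noise).
#'
#' @param v_true True initial rate (signal/s).
#' @param duration Trace length (s), > 0.
#' @param dt Sampling interval (s), > 0.
#' @param baseline Signal offset at t = 0.
#' @param noise_sd_signal Standard deviation of additive signal noise
#'   (signal units).
#' @param seed Integer RNG seed.
#' @param well_id Label carried through to the trace.
#' @param substrate_conc,signal_per_product Optional calibration passed to
#'   [progress_trace()] so that [hydrolysis_fraction()] can be evaluated.
#' @return A [progress_trace()].
#' @export
simulate_progress_trace <- function(v_true, duration = 60, dt = 1,
                                    baseline = 0, noise_sd_signal = 0, seed,
                                    well_id = "sim",
                                    substrate_conc = NA_real_,
                                    signal_per_product = NA_real_) {
  stopifnot(is.numeric(v_true), length(v_true) == 1L)
  if (duration <= 0 || dt <= 0) stop("`duration` and `dt` must be > 0")
  if (missing(seed)) stop("`seed` is mandatory")
  times <- seq(0, duration, by = dt)
  noise <- if (noise_sd_signal > 0)
    .with_seed(seed, stats::rnorm(length(times), 0, noise_sd_signal))
  else 0
  progress_trace(times = times, signal = baseline + v_true * times + noise,
                 well_id = well_id, substrate_conc = substrate_conc,
                 signal_per_product = signal_per_product)
}
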