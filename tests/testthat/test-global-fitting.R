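test_that("noiseless simulated data are a fixed point of the global fit", {
  d <- make_noiseless_dataset()      # inhibitor 5c, E_0 = 1 nM
  fit <- fit_preequilibrium(d)
  expect_equal(fit$convergence, 0L)
  expect_lt(rel_err(fit$estimates$params$k_on, params_5c$k_on), 1e-6)
  expect_lt(rel_err(fit$estimates$params$k_off, params_5c$k_off), 1e-6)
  expect_lt(rel_err(fit$estimates$v_0, 1), 1e-6)
  expect_equal(fit$estimates$params$K_i,
               ki_from_rates(fit$estimates$params$k_on,
                             fit$estimates$params$k_off))
  expect_true(fit$diagnostics$identifiable)
})

test_that("a shared-adjustable E_0 is recovered from noiseless data", {
  d <- make_noiseless_dataset(seed = 7)
  fit <- fit_preequilibrium(d, fit_options(E_0_mode = "shared-adjustable"))
  expect_lt(rel_err(fit$estimates$E_0, 1e-9), 1e-6)
  expect_lt(rel_err(fit$estimates$params$k_on, params_5c$k_on), 1e-6)
  expect_lt(rel_err(fit$estimates$params$k_off, params_5c$k_off), 1e-6)
})

test_that("per-timepoint uninhibited rates are supported and recovered", {
  d <- make_noiseless_dataset()
  fit <- fit_preequilibrium(d, fit_options(v_0_mode = "per-timepoint"))
  expect_length(fit$estimates$v_0, 4L)
  expect_true(all(rel_err(fit$estimates$v_0, 1) < 1e-6))
})

test_that("row order does not change the estimates", {
  d <- make_noiseless_dataset(seed = 3)
  set.seed(99)
  perm <- titration_dataset(as.data.frame(d)[sample(nrow(d)), ],
                            attr(d, "conditions"))
  f1 <- fit_preequilibrium(d)
  f2 <- fit_preequilibrium(perm)
  expect_equal(f1$estimates$params$k_on, f2$estimates$params$k_on,
               tolerance = 1e-9)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-9)
})

test_that("fully equilibrated curve families trigger the identifiability flag", {
  b <- relaxation_rate(params_5c, 1e-9)
  d <- make_noiseless_dataset(timepoints = sort(c(10, 20, 40) / b))
  fit <- fit_preequilibrium(d)
  expect_false(fit$diagnostics$identifiable)
  expect_match(fit$diagnostics$flags, "not separately identifiable")
  # the ratio is still right even though the individual constants are not pinned
  expect_lt(rel_err(fit$estimates$params$K_i, params_5c$K_i), 1e-4)
})

test_that("datasets with a single timepoint or sparse curves are policed", {
  cond <- assay_conditions(1e-9, 900)
  d1 <- simulate_titration(simulation_spec(params_5c, cond, noise_sd = 0,
                                           seed = 1))
  expect_warning(fit_preequilibrium(d1), "one incubation timepoint")
  sparse <- data.frame(time_s = rep(c(300, 900), each = 3),
                       I0 = rep(c(4e-9, 1e-9, 0), 2),
                       rate = rep(c(0.2, 0.5, 1), 2))
  d2 <- titration_dataset(sparse, assay_conditions(1e-9, c(300, 900)))
  expect_error(fit_preequilibrium(d2), "4 distinct")
  # no-inhibitor control enforced at construction
  expect_error(titration_dataset(
    data.frame(time_s = 300, I0 = 1e-9, rate = 0.4),
    assay_conditions(1e-9, 300)), "control")
})

test_that("Morrison fit recovers a noiseless equilibrium curve exactly", {
  grid <- dilution_series(16e-9, 2, 11)
  rates <- residual_rate_eq(1, 2e-9, grid, 0.22e-9)
  fit <- fit_equilibrium(data.frame(I0 = grid, rate = rates), E_0 = 2e-9)
  expect_equal(1e9 * fit$K_i_app, 0.22, tolerance = 1e-6)
  expect_equal(fit$v_0, 1, tolerance = 1e-6)
  # and on the t -> infinity limit of the integrated model it returns k_off/k_on
  rates_inf <- residual_rate_preeq(1, 1e8, 2e-9, grid, params_2d)
  fit_inf <- fit_equilibrium(data.frame(I0 = grid, rate = rates_inf),
                             E_0 = 2e-9)
  expect_lt(rel_err(fit_inf$K_i_app, params_2d$K_i), 1e-4)
})

test_that("curves without inhibition yield a diagnostic, not a number", {
  grid <- dilution_series(16e-9, 2, 11)
  fit <- fit_equilibrium(data.frame(I0 = grid, rate = rep(2, length(grid))),
                         E_0 = 2e-9)
  expect_true(is.na(fit$K_i_app))
  expect_match(fit$diagnostics$flags, "no-inhibition")
})

test_that("equilibrium analysis of a 15-min curve overestimates K_i as expected", {
  rep_2d <- equilibration_bias_report(params_2d, E_0 = 2e-9, t = 900)
  expect_equal(1e9 * rep_2d$K_i_app_t, 0.35, tolerance = 0.06)   # ~0.34 fitted
  expect_equal(1e9 * rep_2d$K_i_true, 0.22, tolerance = 0.01)
  expect_equal(rep_2d$bias_ratio, 1.6, tolerance = 0.05)
  # fully equilibrated: no bias
  rep_inf <- equilibration_bias_report(params_2d, E_0 = 2e-9, t = Inf)
  expect_equal(rep_inf$bias_ratio, 1, tolerance = 1e-4)
  # faster equilibration (k_off x10, same t) shrinks the bias monotonically
  faster <- equilibration_bias_report(
    binding_parameters(params_2d$k_on, 10 * params_2d$k_off), E_0 = 2e-9,
    t = 900)
  expect_lt(abs(faster$bias_ratio - 1), abs(rep_2d$bias_ratio - 1))
})

test_that("noisy replicates return unbiased estimates with honest uncertainties", {
  b <- relaxation_rate(params_5c, 1e-9)
  tps <- sort(c(0.3, 1, 3) / b)
  res <- t(vapply(1:15, function(s) {
    d <- make_noiseless_dataset(timepoints = tps, seed = s, noise_sd = 0.02)
    f <- fit_preequilibrium(d)
    c(f$estimates$params$k_on, f$estimates$params$k_off,
      f$cv_pct[["k_on"]])
  }, numeric(3)))
  expect_lt(rel_err(stats::median(res[, 1]), params_5c$k_on), 0.10)
  expect_lt(rel_err(stats::median(res[, 2]), params_5c$k_off), 0.25)
  expect_lt(stats::median(res[, 3]), 20)   # k_on is precisely determined
})
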