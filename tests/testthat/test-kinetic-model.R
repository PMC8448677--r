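test_that("complex concentration honours the initial condition and the no-inhibitor limit", {
  p <- params_2d
  expect_identical(ei_concentration(0, 2e-9, 2e-9, p), 0)
  expect_identical(ei_concentration(c(0, 10, 1e4), 2e-9, 0, p), c(0, 0, 0))
  expect_equal(residual_rate_preeq(1, 0, 2e-9, 5e-9, p), 1)
  expect_equal(residual_rate_preeq(3.2, 900, 2e-9, 0, p), 3.2)
  expect_equal(residual_rate_eq(3.2, 2e-9, 0, 1e-10), 3.2)
})

test_that("closed form matches the frozen ODE-derived reference point", {
  # inhibitor 2d at E_0 = I_0 = 2 nM, 15 min incubation
  ei <- ei_concentration(900, 2e-9, 2e-9, params_2d)
  expect_lt(rel_err(ei, EI_2D_900S), 1e-8)
  # residual rate is the complementary free-enzyme fraction
  vi <- residual_rate_preeq(1, 900, 2e-9, 2e-9, params_2d)
  expect_equal(vi, 1 - ei / 2e-9, tolerance = 1e-12)
})

test_that("long-time limit of the integrated model is the Morrison occupancy", {
  p <- params_2d
  eq <- ei_equilibrium(2e-9, 2e-9, p$K_i)
  expect_lt(rel_err(ei_concentration(1e7, 2e-9, 2e-9, p), eq), 1e-9)
  expect_equal(ei_concentration(Inf, 2e-9, 2e-9, p), eq, tolerance = 1e-12)
  # across a dilution series the two residual-rate models coincide at t -> inf
  grid <- dilution_series(16e-9, 2, 11)
  v_pre <- residual_rate_preeq(1, 1e8, 2e-9, grid, p)
  v_eq <- residual_rate_eq(1, 2e-9, grid, p$K_i)
  expect_lt(max(abs(v_pre - v_eq)), 1e-9)
})

test_that("equilibrium occupancy trivial limits hold", {
  expect_equal(ei_equilibrium(1e-9, 0, 1e-10), 0)
  # stoichiometric limit: K_i_app -> 0 with excess inhibitor saturates the enzyme
  expect_equal(ei_equilibrium(1e-9, 5e-9, 0), 1e-9)
  expect_equal(residual_rate_eq(1, 1e-9, 1e-9, 0), 0)
})

test_that("occupancy is conserved, monotone in t, and rates monotone in dose", {
  set.seed(11)
  for (i in 1:25) {
    E0 <- 10^runif(1, -11, -7); I0 <- 10^runif(1, -11, -7)
    p <- binding_parameters(10^runif(1, 4, 8), 10^runif(1, -6, -1))
    tt <- sort(10^runif(8, 0, 5))
    ei <- ei_concentration(tt, E0, I0, p)
    expect_true(all(ei >= 0 & ei <= min(E0, I0) * (1 + 1e-12)))
    expect_true(all(diff(ei) >= -1e-12 * min(E0, I0)))
    # residual rate strictly decreasing in I_0 at fixed t > 0
    doses <- dilution_series(100 * E0, 2, 8)
    vi <- residual_rate_preeq(1, tt[4], E0, doses, p)
    expect_true(all(diff(vi) > 0))   # doses are decreasing, so rates rise
    expect_true(all(vi >= 0 & vi <= 1))
  }
})

test_that("degenerate b = 0 branch (k_off = 0, E_0 = I_0) matches its series limit and the rate law", {
  p0 <- binding_parameters(1e6, 0)
  E0 <- 1e-9
  for (tt in c(1, 100, 1e4)) {
    a <- p0$k_on * 2 * E0
    expect_equal(ei_concentration(tt, E0, E0, p0),
                 a^2 * tt / (2 * p0$k_on * (2 + a * tt)), tolerance = 1e-12)
    expect_lt(rel_err(ei_concentration(tt, E0, E0, p0),
                      ei_ode_oracle(tt, E0, E0, p0)), 1e-6)
  }
  # near-degenerate: E_0 ~ I_0 with tiny k_off must not lose precision
  pn <- binding_parameters(1e6, 1e-12)
  expect_lt(rel_err(ei_concentration(1e3, E0, E0 * (1 + 1e-12), pn),
                    ei_ode_oracle(1e3, E0, E0 * (1 + 1e-12), pn)), 1e-6)
})

test_that("apparent/true conversion is the identity at S = 0 and invertible", {
  p <- params_2d
  id <- apparent_from_true(p, S = 0, K_m = 2e-4)
  expect_equal(id$k_on, p$k_on)
  expect_equal(id$k_off, p$k_off)
  # S = K_m doubles K_i, halves k_on, leaves k_off
  app <- apparent_from_true(binding_parameters(1e6, 1e-3), S = 2e-5, K_m = 2e-5)
  expect_equal(app$k_on, 5e5)
  expect_equal(app$k_off, 1e-3)
  expect_equal(app$K_i, 2e-9)
  # closure: ratio identity holds for apparent parameters by construction
  expect_equal(app$K_i, app$k_off / app$k_on, tolerance = 1e-12)
  # round trip to machine precision
  back <- true_from_apparent(app, S = 2e-5, K_m = 2e-5)
  expect_equal(back$k_on, 1e6)
  expect_equal(back$k_off, 1e-3)
  expect_error(apparent_from_true(p, S = 1e-5, K_m = -1), "K_m")
})

test_that("K_i from rate constants reproduces printed values and rejects bad input", {
  expect_equal(round(1e9 * ki_from_rates(3.86e5, 7.0e-4), 1), 1.8)
  expect_equal(round(1e9 * ki_from_rates(1.37e6, 2.99e-4), 2), 0.22)
  expect_identical(ki_from_rates(1e6, 0), 0)
  expect_error(ki_from_rates(0, 1e-4), "k_on")
  expect_error(ki_from_rates(1e6, -1), "k_off")
})

test_that("domain errors are raised for invalid concentrations and times", {
  p <- params_2d
  expect_error(ei_concentration(-1, 2e-9, 2e-9, p), "t")
  expect_error(ei_concentration(10, -2e-9, 2e-9, p), "E_0")
  expect_error(ei_concentration(10, 2e-9, -1e-9, p), "I_0")
  expect_error(binding_parameters(-1e6, 1e-4), "k_on")
  expect_error(binding_parameters(1e6, -1e-4), "k_off")
  expect_error(assay_conditions(1e-9, c(300, 200)), "timepoints")
  expect_error(residual_rate_preeq(0, 900, 2e-9, 2e-9, p), "v_0")
})
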