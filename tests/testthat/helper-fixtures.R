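# Shared fixtures: published rate constants of the plasma kallikrein
# bicyclic-peptide inhibitors used as reference inputs, plus small
# constructors for synthetic datasets.

# k_on (M^-1 s^-1), k_off (s^-1), and the printed K_i (nM) with its number
# of printed decimals, per inhibitor
kallikrein_inhibitors <- list(
  `1b` = list(k_on = 3.86e5, k_off = 7.0e-4,  ki_nM = 1.8,  decimals = 1),
  `2b` = list(k_on = 5.7e6,  k_off = 5.82e-4, ki_nM = 0.10, decimals = 2),
  `2c` = list(k_on = 2.40e6, k_off = 8.2e-4,  ki_nM = 0.34, decimals = 2),
  `2d` = list(k_on = 1.37e6, k_off = 2.99e-4, ki_nM = 0.22, decimals = 2),
  `4b` = list(k_on = 1.06e7, k_off = 1.49e-3, ki_nM = 0.14, decimals = 2),
  `5c` = list(k_on = 3.5e6,  k_off = 1.92e-4, ki_nM = 0.061, decimals = 3))

params_2d <- binding_parameters(1.37e6, 2.99e-4)
params_5c <- binding_parameters(3.5e6, 1.92e-4)

# [EI]_t for 2d at E_0 = I_0 = 2 nM, t = 900 s: frozen reference obtained
# before the closed form was written, by adaptive RK45 integration of the
# binding rate law at rtol 1e-10
EI_2D_900S <- 1.2917469198e-9

# relaxation rate of the binding step at total concentrations (E_0, I_0)
relaxation_rate <- function(params, E_0, I_0 = E_0) {
  a <- params$k_on * (E_0 + I_0) + params$k_off
  sqrt(a^2 - 4 * params$k_on^2 * E_0 * I_0)
}

make_noiseless_dataset <- function(params = params_5c, E_0 = 1e-9,
                                   timepoints = c(300, 900, 2700, 7200),
                                   seed = 1, noise_sd = 0, ...) {
  cond <- assay_conditions(E_0, timepoints)
  simulate_titration(simulation_spec(params, cond, noise_sd = noise_sd,
                                     seed = seed, ...))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
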