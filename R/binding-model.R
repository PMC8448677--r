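# Closed-form 1:1 binding kinetics and the Morrison tight-binding model.
#
# All concentrations are mol/L, times s, rates of the binding step s^-1 or
# M^-1 s^-1.  The integrated model gives the enzyme-inhibitor complex
# concentration [EI]_t of the reaction E + I <-> EI started from free
# species, without any excess-inhibitor simplification, so it remains valid
# for tight binders where I_0 ~ E_0.

# Vectorised core.  E0, kon, koff scalars; t and I0 vectors of equal length.
# Uses the algebraically equivalent, cancellation-free form
#   [EI]_t = (a - b) * (1 - e^{-bt}) /
#            (2 kon * ((1 - e^{-bt}) + (2b/(a+b)) e^{-bt}))
# with a = kon (E0 + I0) + koff, b = sqrt(a^2 - 4 kon^2 E0 I0).
# The radicand is computed exactly nonnegative as
#   (kon (sqrt(E0) - sqrt(I0))^2 + koff) * (a + 2 kon sqrt(E0 I0)).
# Only e^{-bt} appears, so overflow is impossible; the b -> 0 limit of this
# form tends smoothly to a^2 t / (2 kon (2 + a t)), kept as an explicit
# branch for b == 0 exactly.
.ei_core <- function(t, E0, I0, kon, koff) {
  s <- 2 * kon * sqrt(E0 * I0)
  a <- kon * (E0 + I0) + koff
  b <- sqrt((kon * (sqrt(E0) - sqrt(I0))^2 + koff) * (a + s))
  out <- numeric(length(t))

  zero <- I0 == 0 | t == 0
  deg <- !zero & b == 0                       # koff = 0 and E0 = I0 exactly
  gen <- !zero & !deg

  if (any(deg)) {
    ad <- a[deg]; td <- t[deg]
    out[deg] <- ifelse(is.infinite(td), ad / (2 * kon),
                       ad^2 * td / (2 * kon * (2 + ad * td)))
  }
  if (any(gen)) {
    ag <- a[gen]; bg <- b[gen]; tg <- t[gen]
    ebt <- exp(-bg * tg)                       # 0 when bg*tg > ~745
    e1 <- -expm1(-bg * tg)                     # 1 - e^{-bt}, accurate near 0
    den <- e1 + (2 * bg / (ag + bg)) * ebt     # both terms >= 0
    out[gen] <- (ag - bg) * e1 / (2 * kon * den)
  }
  out
}

#' Enzyme-inhibitor complex concentration at time t (integrated 1:1 model)
#'
#' Closed-form solution of the binding rate law
#' `d[EI]/dt = k_on (E_0 - [EI]) (I_0 - [EI]) - k_off [EI]` starting from
#' `[EI]_0 = 0`, i.e. enzyme and inhibitor mixed at time zero.  No
#' excess-inhibitor approximation is made, so the expression is exact for
#' tight-binding inhibitors with `I_0 ~ E_0`.
#'
#' `t` and `I_0` may be vectors (recycled against each other); `t = Inf`
#' returns the equilibrium complex concentration.
#'
#' @param t Incubation time (s), >= 0; `Inf` allowed.
#' @param E_0 Total enzyme concentration (mol/L), > 0.
#' @param I_0 Total inhibitor concentration (mol/L), >= 0.
#' @param params A [binding_parameters()] object.
#' @return `[EI]_t` in mol/L, bounded by `[0, min(E_0, I_0)]` and
#'   nondecreasing in `t`.
#' @seealso [ei_equilibrium()] for the t -> infinity limit,
#'   [ei_ode_oracle()] for a direct numerical integration of the rate law.
#' @examples
#' p <- binding_parameters(1.37e6, 2.99e-4)
#' ei_concentration(900, E_0 = 2e-9, I_0 = 2e-9, params = p)
#' @export
ei_concentration <- function(t, E_0, I_0, params) {
  stopifnot(inherits(params, "binding_parameters"),
            is.numeric(t), is.numeric(E_0), length(E_0) == 1L, is.numeric(I_0))
  if (!is.finite(E_0) || E_0 <= 0) stop("`E_0` must be positive (mol/L)")
  if (any(is.na(t)) || any(t < 0)) stop("`t` must be >= 0 (s)")
  if (any(!is.finite(I_0)) || any(I_0 < 0)) stop("`I_0` must be >= 0 (mol/L)")
  n <- max(length(t), length(I_0))
  .ei_core(rep_len(as.numeric(t), n), E_0, rep_len(as.numeric(I_0), n),
           params$k_on, params$k_off)
}

#' Equilibrium enzyme-inhibitor complex concentration (Morrison)
#'
#' The quadratic-root complex concentration of the tight-binding
#' (Morrison) equilibrium model,
#' `((E_0 + I_0 + K_i_app) - sqrt((E_0 + I_0 + K_i_app)^2 - 4 E_0 I_0)) / 2`.
#' Equals the `t -> Inf` limit of [ei_concentration()] when
#' `K_i_app = k_off / k_on`.
#'
#' The radicand is evaluated in the cancellation-free form
#' `(E_0 - I_0)^2 + K_i_app^2 + 2 K_i_app (E_0 + I_0)`, which is
#' nonnegative for all valid inputs; any tiny negative value from round-off
#' is clamped to zero with a warning.
#'
#' @param E_0 Total enzyme concentration (mol/L), > 0.
#' @param I_0 Total inhibitor concentration(s) (mol/L), >= 0; vectorised.
#' @param K_i_app Apparent equilibrium inhibition constant (mol/L), >= 0.
#' @return Equilibrium `[EI]` in mol/L.
#' @export
ei_equilibrium <- function(E_0, I_0, K_i_app) {
  stopifnot(is.numeric(E_0), length(E_0) == 1L, is.numeric(I_0),
            is.numeric(K_i_app), length(K_i_app) == 1L)
  if (!is.finite(E_0) || E_0 <= 0) stop("`E_0` must be positive (mol/L)")
  if (any(I_0 < 0)) stop("`I_0` must be >= 0 (mol/L)")
  if (!is.finite(K_i_app) || K_i_app < 0) stop("`K_i_app` must be >= 0 (mol/L)")
  rad <- (E_0 - I_0)^2 + K_i_app^2 + 2 * K_i_app * (E_0 + I_0)
  if (any(rad < 0)) {
    warning("negative radicand clamped to zero in equilibrium occupancy")
    rad <- pmax(rad, 0)
  }
  ((E_0 + I_0 + K_i_app) - sqrt(rad)) / 2
}

#' Residual enzymatic rate under pre-equilibrium conditions
#'
#' The observable of a pre-equilibrium titration: the initial rate of
#' substrate hydrolysis after incubating enzyme and inhibitor for time `t`,
#' `v_i = v_0 (E_0 - [EI]_t) / E_0`, with `[EI]_t` from the integrated 1:1
#' model.  Because the curve is recorded before equilibrium, its shape
#' carries information on `k_on` and `k_off` separately, not just their
#' ratio.
#'
#' @inheritParams ei_concentration
#' @param v_0 Uninhibited rate (signal/s), > 0.
#' @return Inhibited rate(s) `v_i` in `[0, v_0]`.
#' @export
residual_rate_preeq <- function(v_0, t, E_0, I_0, params) {
  if (!is.numeric(v_0) || length(v_0) != 1L || !is.finite(v_0) || v_0 <= 0)
    stop("`v_0` must be a positive rate")
  v_0 * (E_0 - ei_concentration(t, E_0, I_0, params)) / E_0
}

#' Residual enzymatic rate at equilibrium (Morrison tight-binding curve)
#'
#' `v_i = v_0 (E_0 - [EI]_eq) / E_0` with the quadratic-root equilibrium
#' occupancy of [ei_equilibrium()].  This is the model conventionally
#' fitted to single inhibition curves assumed to be fully equilibrated.
#'
#' @inheritParams ei_equilibrium
#' @param v_0 Uninhibited rate (signal/s), > 0.
#' @return Inhibited rate(s) `v_i` in `[0, v_0]`.
#' @export
residual_rate_eq <- function(v_0, E_0, I_0, K_i_app) {
  if (!is.numeric(v_0) || length(v_0) != 1L || !is.finite(v_0) || v_0 <= 0)
    stop("`v_0` must be a positive rate")
  v_0 * (E_0 - ei_equilibrium(E_0, I_0, K_i_app)) / E_0
}

#' Convert true binding parameters to apparent ones (competitive inhibition)
#'
#' In the presence of a competitive substrate at concentration `S`, the
#' measured constants are apparent: `k_on_app = k_on / (1 + S/K_m)`,
#' `k_off_app = k_off`, hence `K_i_app = K_i (1 + S/K_m)`.  With `S = 0`
#' this is the identity, the regime in which apparent values equal true
#' values (`S << K_m`).
#'
#' @param params True [binding_parameters()].
#' @param S Substrate concentration (mol/L), >= 0.
#' @param K_m Michaelis-Menten constant (mol/L), > 0.
#' @return Apparent [binding_parameters()].
#' @seealso [true_from_apparent()] for the inverse.
#' @export
apparent_from_true <- function(params, S, K_m) {
  stopifnot(inherits(params, "binding_parameters"))
  .check_sk(S, K_m)
  binding_parameters(k_on = params$k_on / (1 + S / K_m), k_off = params$k_off)
}

#' Recover true binding parameters from apparent ones (competitive)
#'
#' Inverse of [apparent_from_true()]: `k_on = k_on_app (1 + S/K_m)`,
#' `k_off = k_off_app`.
#'
#' @param params Apparent [binding_parameters()].
#' @inheritParams apparent_from_true
#' @return True [binding_parameters()].
#' @export
true_from_apparent <- function(params, S, K_m) {
  stopifnot(inherits(params, "binding_parameters"))
  .check_sk(S, K_m)
  binding_parameters(k_on = params$k_on * (1 + S / K_m), k_off = params$k_off)
}

.check_sk <- function(S, K_m) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0)
    stop("`S` must be a nonnegative concentration (mol/L)")
  if (!is.numeric(K_m) || length(K_m) != 1L || !is.finite(K_m) || K_m <= 0)
    stop("`K_m` must be a positive concentration (mol/L)")
  invisible(TRUE)
}

#' Equilibrium inhibition constant from rate constants
#'
#' `K_i = k_off / k_on`, the dissociation constant of the enzyme-inhibitor
#' complex; its inverse relation defines the consistency between kinetic
#' and equilibrium characterisation of an inhibitor.
#'
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @param k_off Dissociation rate constant (s^-1), >= 0.
#' @return `K_i` in mol/L.
#' @examples
#' 1e9 * ki_from_rates(3.86e5, 7.0e-4)   # 1.8 nM
#' @export
ki_from_rates <- function(k_on, k_off) {
  if (any(!is.finite(k_on)) || any(k_on <= 0)) stop("`k_on` must be > 0")
  if (any(!is.finite(k_off)) || any(k_off < 0)) stop("`k_off` must be >= 0")
  k_off / k_on
}
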