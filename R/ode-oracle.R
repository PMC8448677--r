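#' Numerical reference solution of the 1:1 binding rate law
#'
#' Integrates `d[EI]/dt = k_on (E_0 - [EI]) (I_0 - [EI]) - k_off [EI]` from
#' `[EI]_0 = 0` with an adaptive embedded Runge-Kutta scheme (Cash-Karp
#' 4(5)).  This is a brute-force cross-check for [ei_concentration()]; it
#' never touches the closed form, so agreement between the two validates
#' the analytical solution independently.
#'
#' Explicit stepping is stability-limited once the transient has decayed,
#' so integration is cut off after 60 relaxation times of the fixed point
#' (fixed point and local decay rate are obtained from the rate law
#' itself); beyond that point the solution is stationary to well below
#' double precision.
#'
#' @inheritParams ei_concentration
#' @param t Scalar time (s), >= 0, finite.
#' @param rtol Relative local error tolerance per step.
#' @param max_steps Step budget; exceeding it raises an error carrying the
#'   time reached, for diagnosis.
#' @return `[EI]_t` in mol/L.
#' @export
ei_ode_oracle <- function(t, E_0, I_0, params, rtol = 1e-8, max_steps = 2e6) {
  stopifnot(inherits(params, "binding_parameters"),
            is.numeric(t), length(t) == 1L, is.finite(t), t >= 0,
            is.numeric(E_0), length(E_0) == 1L, E_0 > 0,
            is.numeric(I_0), length(I_0) == 1L, I_0 >= 0)
  kon <- params$k_on; koff <- params$k_off
  if (t == 0 || I_0 == 0) return(0)

  # fixed point x* of the rate law (smaller root of the quadratic
  # kon x^2 - (kon(E0+I0)+koff) x + kon E0 I0 = 0) and its local decay
  # rate lambda = -f'(x*); used only to bound the integration horizon.
  p <- E_0 + I_0 + koff / kon
  xeq <- 2 * E_0 * I_0 / (p + sqrt(p * p - 4 * E_0 * I_0))
  lambda <- kon * (E_0 - xeq) + kon * (I_0 - xeq) + koff
  t_end <- min(t, 60 / lambda)

  atol <- rtol * min(E_0, I_0) * 1e-3
  x <- 0; tt <- 0
  h <- min(t_end, 0.1 / (kon * (E_0 + I_0) + koff))
  steps <- 0L
  f <- function(x) kon * (E_0 - x) * (I_0 - x) - koff * x
  while (tt < t_end) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop(sprintf("ODE oracle exceeded %d steps at t = %.3g of %.3g s (h = %.3g)",
                   as.integer(max_steps), tt, t_end, h))
    if (tt + h > t_end) h <- t_end - tt
    k1 <- f(x)
    k2 <- f(x + h * k1 / 5)
    k3 <- f(x + h * (3 * k1 + 9 * k2) / 40)
    k4 <- f(x + h * (0.3 * k1 - 0.9 * k2 + 1.2 * k3))
    k5 <- f(x + h * (-11 * k1 / 54 + 2.5 * k2 - 70 * k3 / 27 + 35 * k4 / 27))
    k6 <- f(x + h * (1631 * k1 / 55296 + 175 * k2 / 512 + 575 * k3 / 13824 +
                       44275 * k4 / 110592 + 253 * k5 / 4096))
    x5 <- x + h * (37 * k1 / 378 + 250 * k3 / 621 + 125 * k4 / 594 +
                     512 * k6 / 1771)
    x4 <- x + h * (2825 * k1 / 27648 + 18575 * k3 / 48384 +
                     13525 * k4 / 55296 + 277 * k5 / 14336 + k6 / 4)
    err <- abs(x5 - x4)
    sc <- rtol * abs(x5) + atol
    if (err <= sc) { tt <- tt + h; x <- x5 }
    h <- h * min(5, max(0.1, 0.9 * (sc / max(err, 1e-300))^0.2))
  }
  x
}
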