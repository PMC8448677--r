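#' Binding parameters of a 1:1 enzyme-inhibitor interaction
#'
#' Bundles the second-order association rate constant `k_on`, the
#' first-order dissociation rate constant `k_off`, and the equilibrium
#' inhibition constant `K_i = k_off / k_on` for one enzyme-inhibitor pair.
#' All values are SI: `k_on` in M^-1 s^-1, `k_off` in s^-1, `K_i` in mol/L.
#' `K_i` is always derived, never stored independently, so the ratio
#' identity holds by construction.
#'
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @param k_off Dissociation rate constant (s^-1), >= 0.
#'
#' @return An object of class `binding_parameters`: a list with elements
#'   `k_on`, `k_off` and `K_i`.
#' @examples
#' binding_parameters(k_on = 1.37e6, k_off = 2.99e-4)
#' @export
binding_parameters <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_off), length(k_off) == 1L)
  if (!is.finite(k_on) || k_on <= 0)
    stop("`k_on` must be a finite positive rate constant (M^-1 s^-1)")
  if (!is.finite(k_off) || k_off < 0)
    stop("`k_off` must be a finite nonnegative rate constant (s^-1)")
  structure(list(k_on = k_on, k_off = k_off, K_i = k_off / k_on),
            class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("1:1 binding parameters\n  k_on  = %.4g M^-1 s^-1\n  k_off = %.4g s^-1\n  K_i   = %.4g nM (k_off/k_on)\n",
              x$k_on, x$k_off, 1e9 * x$K_i))
  invisible(x)
}

#' Assay conditions for a pre-equilibrium titration experiment
#'
#' @param E_0 Total enzyme concentration (mol/L), > 0.
#' @param timepoints Incubation times (s) at which inhibition curves are
#'   recorded; strictly positive and strictly increasing.
#' @param S Substrate concentration (mol/L) during the readout, >= 0.
#'   Defaults to 0, i.e. the competitive-inhibition correction is off and
#'   fitted constants are reported as apparent values (valid when
#'   `S << K_m`).
#' @param K_m Michaelis-Menten constant of the enzyme for this substrate
#'   (mol/L). Only required when `S > 0`.
#'
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(E_0, timepoints, S = 0, K_m = NA_real_) {
  stopifnot(is.numeric(E_0), length(E_0) == 1L, is.numeric(timepoints))
  if (!is.finite(E_0) || E_0 <= 0)
    stop("`E_0` must be a finite positive concentration (mol/L)")
  if (length(timepoints) < 1L || any(!is.finite(timepoints)) ||
      any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE))
    stop("`timepoints` must be strictly positive and strictly increasing (s)")
  if (!is.na(S) && S < 0) stop("`S` must be >= 0")
  if (S > 0 && (is.na(K_m) || K_m <= 0))
    stop("`K_m` must be a positive concentration when `S` > 0")
  structure(list(E_0 = E_0, S = S, K_m = K_m, timepoints = as.numeric(timepoints)),
            class = "assay_conditions")
}

#' Titration dataset: initial rates by incubation time and inhibitor dose
#'
#' The observable of the global fit: one initial rate of substrate
#' hydrolysis per (incubation timepoint, total inhibitor concentration)
#' pair, held as a long-format data frame with columns `time_s` (s),
#' `I0` (mol/L) and `rate` (signal/s).
#'
#' @param records Data frame with numeric columns `time_s`, `I0`, `rate`.
#' @param conditions An [assay_conditions()] object; every `time_s` value
#'   must appear in `conditions$timepoints`.
#' @param provenance Free-text descriptor of where the records came from
#'   (a simulation spec, a file path, ...).
#'
#' @return Object of class `titration_dataset` (a data frame with
#'   attributes `conditions` and `provenance`).
#' @export
titration_dataset <- function(records, conditions,
                              provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  needed <- c("time_s", "I0", "rate")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("`records` is missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cl in needed)
    if (!is.numeric(records[[cl]])) stop("column `", cl, "` must be numeric")
  if (!inherits(conditions, "assay_conditions"))
    stop("`conditions` must be an assay_conditions object")
  if (any(!is.finite(records$rate))) stop("rates must be finite")
  if (any(records$I0 < 0)) stop("inhibitor concentrations must be >= 0")
  if (!all(records$time_s %in% conditions$timepoints))
    stop("every `time_s` in records must appear in conditions$timepoints")
  for (tp in unique(records$time_s))
    if (!any(records$I0[records$time_s == tp] == 0))
      stop(sprintf("timepoint %g s lacks an I0 = 0 (no-inhibitor) control", tp))
  structure(as.data.frame(records[, needed, drop = FALSE]),
            conditions = conditions, provenance = provenance,
            class = c("titration_dataset", "data.frame"))
}

#' @export
print.titration_dataset <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("Pre-equilibrium titration dataset: %d rates, %d timepoint(s), E_0 = %.3g nM\n",
              nrow(x), length(unique(x$time_s)), 1e9 * cond$E_0))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
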