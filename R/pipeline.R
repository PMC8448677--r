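# Pipeline glue: simulate -> (rates) -> fit -> report, driven by a JSON
# run config.  Every stage emits one machine-parsable log line; all
# randomness flows from config seeds; reports state their units (nM,
# M^-1 s^-1, s^-1 -- never bare SI mol/L in human-facing tables).

.log_stage <- function(stage, ...) {
  message(sprintf("[preqkin] stage=%s %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

.cfg_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) stop("run config is missing required field `", key, "`")
    return(default)
  }
  val
}

#' Run one pipeline stage from a run configuration
#'
#' Modes:
#' \describe{
#'   \item{`simulate`}{Generate a synthetic titration with
#'     [simulate_titration()] and write the tidy rates CSV.  Fields:
#'     `k_on`, `k_off`, `E_0`, `timepoints`, `seed` (required); `top_I0`,
#'     `dilution_factor`, `n_dilutions`, `v_0`, `noise_sd`, `conc_unit`,
#'     `out` (defaults: reference grid, 2% noise, nM, `rates.csv`).}
#'   \item{`rates`}{Extract initial rates from per-well trace CSVs listed
#'     in a manifest CSV (`manifest` with columns `file`, `time_s`,
#'     `inhibitor_conc`), writing a rates CSV with QC columns.  Optional:
#'     `window`, `r2_threshold`, `substrate_conc`, `signal_per_product`,
#'     `blank` (trace file subtracted pointwise), `conc_unit`.}
#'   \item{`fit`}{Globally fit the pre-equilibrium model to a rates CSV
#'     (`in`, `E_0`, `conc_unit` required) and write `fit_report.csv`,
#'     `fit_report.txt` and `kon_koff_scatter.csv` to `out_dir`.
#'     Optional: `E_0_mode`, `v_0_mode`, `S`, `K_m` (supplying both turns
#'     on the competitive apparent-to-true conversion).}
#'   \item{`bias-report`}{Run [equilibration_bias_report()] (`k_on`,
#'     `k_off`, `E_0`, `t` required) and write `bias_report.txt`.}
#' }
#'
#' @param config A named list, or a path to a JSON file for
#'   [read_run_config()].
#' @return Invisibly, a named list of artifact paths (and the main result
#'   object); stops with a descriptive error on any stage failure.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  mode <- .cfg_get(config, "mode", required = TRUE)
  switch(mode,
         "simulate" = .stage_simulate(config),
         "rates" = .stage_rates(config),
         "fit" = .stage_fit(config),
         "bias-report" = .stage_bias(config),
         stop("unknown mode `", mode,
              "`; expected simulate, rates, fit or bias-report"))
}

.stage_simulate <- function(config) {
  params <- binding_parameters(.cfg_get(config, "k_on", required = TRUE),
                               .cfg_get(config, "k_off", required = TRUE))
  cond <- assay_conditions(
    E_0 = .cfg_get(config, "E_0", required = TRUE),
    timepoints = as.numeric(.cfg_get(config, "timepoints",
                                     default = c(300, 900, 2700, 7200))))
  spec <- simulation_spec(
    params, cond,
    top_I0 = .cfg_get(config, "top_I0", default = 16e-9),
    dilution_factor = .cfg_get(config, "dilution_factor", default = 2),
    n_dilutions = .cfg_get(config, "n_dilutions", default = 11),
    v_0_true = .cfg_get(config, "v_0", default = 1),
    noise_sd = .cfg_get(config, "noise_sd", default = 0.02),
    seed = .cfg_get(config, "seed", required = TRUE))
  data <- simulate_titration(spec)
  out <- .cfg_get(config, "out", default = "rates.csv")
  write_rates_csv(data, out, conc_unit = .cfg_get(config, "conc_unit", "nM"))
  .log_stage("simulate", n_rates = nrow(data), seed = spec$seed,
             out = out, status = "ok")
  invisible(list(rates_csv = out, dataset = data))
}

.stage_rates <- function(config) {
  manifest_path <- .cfg_get(config, "manifest", required = TRUE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "time_s", "inhibitor_conc") %in% names(man)))
    stop("trace manifest must have columns file, time_s, inhibitor_conc")
  fac <- .conc_factor(.cfg_get(config, "conc_unit", "nM"))
  window <- as.numeric(.cfg_get(config, "window", default = c(0, 60)))
  blank_path <- .cfg_get(config, "blank")
  blank <- if (!is.null(blank_path)) read_progress_trace_csv(blank_path)
  base_dir <- dirname(manifest_path)

  rows <- lapply(seq_len(nrow(man)), function(i) {
    fp <- man$file[i]
    if (!file.exists(fp)) fp <- file.path(base_dir, man$file[i])
    tr <- read_progress_trace_csv(
      fp, well_id = man$file[i],
      substrate_conc = .cfg_get(config, "substrate_conc", NA_real_),
      signal_per_product = .cfg_get(config, "signal_per_product", NA_real_))
    est <- fit_initial_rate(tr, window = window, blank = blank,
                            r2_threshold = .cfg_get(config, "r2_threshold", 0.98))
    data.frame(time_s = man$time_s[i],
               inhibitor_conc = man$inhibitor_conc[i],
               rate = est$rate, r_squared = est$r_squared,
               qc_pass = est$qc_pass)
  })
  res <- do.call(rbind, rows)
  out <- .cfg_get(config, "out", default = "rates.csv")
  disk <- res
  for (cl in c("time_s", "inhibitor_conc", "rate", "r_squared"))
    disk[[cl]] <- formatC(res[[cl]], digits = 15, format = "g")
  utils::write.csv(disk, out, row.names = FALSE, quote = FALSE)
  .log_stage("rates", n_traces = nrow(man), n_qc_fail = sum(!res$qc_pass),
             out = out, status = "ok")
  invisible(list(rates_csv = out, rates = res, conc_factor = fac))
}

.stage_fit <- function(config) {
  data <- read_rates_csv(.cfg_get(config, "in", required = TRUE),
                         E_0 = .cfg_get(config, "E_0", required = TRUE),
                         conc_unit = .cfg_get(config, "conc_unit",
                                              required = TRUE),
                         S = .cfg_get(config, "S", 0),
                         K_m = .cfg_get(config, "K_m", NA_real_))
  opts <- fit_options(E_0_mode = .cfg_get(config, "E_0_mode", "fixed"),
                      v_0_mode = .cfg_get(config, "v_0_mode", "shared"))
  fit <- fit_preequilibrium(data, opts)
  out_dir <- .cfg_get(config, "out_dir", default = ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- write_fit_report(fit, out_dir,
                            S = .cfg_get(config, "S", 0),
                            K_m = .cfg_get(config, "K_m", NA_real_))
  .log_stage("fit", n_points = fit$n_points, convergence = fit$convergence,
             rss = formatC(fit$rss, digits = 6, format = "g"),
             identifiable = fit$diagnostics$identifiable, status = "ok")
  invisible(c(paths, list(fit = fit)))
}

.stage_bias <- function(config) {
  params <- binding_parameters(.cfg_get(config, "k_on", required = TRUE),
                               .cfg_get(config, "k_off", required = TRUE))
  rep <- equilibration_bias_report(
    params,
    E_0 = .cfg_get(config, "E_0", required = TRUE),
    t = .cfg_get(config, "t", required = TRUE),
    grid = if (!is.null(config$grid)) as.numeric(config$grid)
    else dilution_series(16e-9, 2, 11))
  out <- .cfg_get(config, "out", default = "bias_report.txt")
  lines <- c(
    "Equilibration bias of Morrison (equilibrium) analysis",
    sprintf("true k_on  = %.6g M^-1 s^-1", params$k_on),
    sprintf("true k_off = %.6g s^-1", params$k_off),
    sprintf("true K_i = k_off/k_on = %.4g nM", 1e9 * rep$K_i_true),
    sprintf("incubation time t = %g s", rep$t),
    sprintf("fitted apparent K_i at t = %.4g nM", 1e9 * rep$K_i_app_t),
    sprintf("bias ratio (fitted / true) = %.3f", rep$bias_ratio))
  writeLines(lines, out)
  .log_stage("bias-report",
             ki_app_nM = formatC(1e9 * rep$K_i_app_t, digits = 4, format = "g"),
             ki_true_nM = formatC(1e9 * rep$K_i_true, digits = 4, format = "g"),
             out = out, status = "ok")
  invisible(list(report_txt = out, report = rep))
}

#' Write fit reports in conventional units
#'
#' Emits `fit_report.csv` (one row per parameter: estimate, SE, CV%, in
#' k_on M^-1 s^-1 / k_off s^-1 / K_i nM / E_0 nM), a human-readable
#' `fit_report.txt` stating bounds, starts and convergence, and
#' `kon_koff_scatter.csv` (one row per fit: the k_on-vs-k_off plot
#' coordinates with error bars, the conventional kinetic map of inhibitor
#' potency).
#'
#' @param fit A [fit_preequilibrium()] result.
#' @param out_dir Output directory.
#' @param S,K_m When both are supplied (mol/L), the competitive
#'   apparent-to-true conversion is applied and true values are reported
#'   alongside the apparent ones.
#' @return Named list of the three file paths, invisibly.
#' @export
write_fit_report <- function(fit, out_dir = ".", S = 0, K_m = NA_real_) {
  stopifnot(inherits(fit, "preqkin_fit"))
  p <- fit$estimates$params
  tab <- data.frame(
    parameter = c("k_on", "k_off", "K_i", "E_0"),
    estimate = c(p$k_on, p$k_off, 1e9 * p$K_i, 1e9 * fit$estimates$E_0),
    se = c(fit$se$k_on, fit$se$k_off, 1e9 * fit$se$K_i, 1e9 * fit$se$E_0),
    cv_pct = unname(fit$cv_pct),
    unit = c("M^-1 s^-1", "s^-1", "nM", "nM"))
  correct <- S > 0 && !is.na(K_m) && K_m > 0
  if (correct) {
    true_p <- true_from_apparent(p, S, K_m)
    tab <- rbind(tab, data.frame(
      parameter = c("k_on_true", "k_off_true", "K_i_true"),
      estimate = c(true_p$k_on, true_p$k_off, 1e9 * true_p$K_i),
      se = NA_real_, cv_pct = NA_real_,
      unit = c("M^-1 s^-1", "s^-1", "nM")))
  }
  csv_path <- file.path(out_dir, "fit_report.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)

  txt_path <- file.path(out_dir, "fit_report.txt")
  v0 <- fit$estimates$v_0
  writeLines(c(
    "Pre-equilibrium global fit report",
    "=================================",
    sprintf("k_on  = %.4g M^-1 s^-1 (SE %.3g, CV %.1f%%)",
            p$k_on, fit$se$k_on, fit$cv_pct["k_on"]),
    sprintf("k_off = %.4g s^-1 (SE %.3g, CV %.1f%%)",
            p$k_off, fit$se$k_off, fit$cv_pct["k_off"]),
    sprintf("K_i = k_off/k_on = %.4g nM (SE %.3g nM)",
            1e9 * p$K_i, 1e9 * fit$se$K_i),
    sprintf("residence time 1/k_off = %.4g s", 1 / p$k_off),
    sprintf("E_0 = %.4g nM (%s)", 1e9 * fit$estimates$E_0,
            fit$options$E_0_mode),
    paste0("v_0 (", fit$options$v_0_mode, "): ",
           paste(sprintf("%s=%.5g", names(v0), v0), collapse = ", ")),
    if (correct) sprintf("competitive correction applied with S = %.3g M, K_m = %.3g M",
                         S, K_m)
    else "no substrate correction (S/K_m treated as 0; values are apparent)",
    sprintf("RSS = %.6g over %d points; residual SD = %.4g",
            fit$rss, fit$n_points, fit$diagnostics$sigma),
    sprintf("convergence code %d; best of %d multistarts (log10 k_on in [%g, %g], log10 k_off in [%g, %g])",
            fit$convergence, fit$start$n_starts,
            .LKON_BOUNDS[1], .LKON_BOUNDS[2],
            .LKOFF_BOUNDS[1], .LKOFF_BOUNDS[2]),
    if (length(fit$diagnostics$flags))
      paste("NOTE:", fit$diagnostics$flags) else "identifiability: ok"),
    txt_path)

  scatter_path <- file.path(out_dir, "kon_koff_scatter.csv")
  utils::write.csv(data.frame(
    k_on = p$k_on, k_on_se = fit$se$k_on,
    k_off = p$k_off, k_off_se = fit$se$k_off,
    K_i_nM = 1e9 * p$K_i, K_i_se_nM = 1e9 * fit$se$K_i),
    scatter_path, row.names = FALSE, quote = FALSE)

  invisible(list(fit_report_csv = csv_path, fit_report_txt = txt_path,
                 kon_koff_scatter_csv = scatter_path))
}
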