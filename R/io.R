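# File contracts: tidy long-format rates CSV (one rate per row), per-well
# progress trace CSV, and a JSON run configuration.  Concentrations on
# disk carry a declared unit; everything in memory is SI (mol/L).

.CONC_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

.conc_factor <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% names(.CONC_FACTORS))
    stop("concentration unit must be one of: ",
         paste(names(.CONC_FACTORS), collapse = ", "))
  .CONC_FACTORS[[unit]]
}

#' Read a tidy rates CSV into a titration dataset
#'
#' Expected header: `time_s`, `inhibitor_conc`, `rate`, optionally
#' `replicate` and `qc_pass`.  Rows with `qc_pass == FALSE` are excluded
#' (their count is logged); concentrations are converted from the declared
#' unit to mol/L.
#'
#' @param path CSV file path.
#' @param E_0 Total enzyme concentration (mol/L) of the experiment the
#'   file describes; stored in the dataset conditions.
#' @param conc_unit Unit of the `inhibitor_conc` column: one of
#'   `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @param S,K_m Optional substrate concentration and Michaelis constant
#'   (mol/L) for apparent-to-true conversion downstream.
#' @return A [titration_dataset()].
#' @export
read_rates_csv <- function(path, E_0, conc_unit = "M", S = 0, K_m = NA_real_) {
  if (!file.exists(path)) stop("rates file not found: ", path)
  fac <- .conc_factor(conc_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "inhibitor_conc", "rate")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("rates CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cl in needed) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(df[[cl]])))
      stop("column `", cl, "` in ", path, " contains unparseable values")
  }
  if ("qc_pass" %in% names(df)) {
    bad <- !as.logical(df$qc_pass)
    if (any(bad)) {
      message(sprintf("[preqkin] stage=read_rates excluded=%d of %d rows failing QC",
                      sum(bad), nrow(df)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  if (!nrow(df)) stop("no usable rows in ", path)
  records <- data.frame(time_s = df$time_s, I0 = df$inhibitor_conc * fac,
                        rate = df$rate)
  if (!any(records$I0 == 0))
    stop("rates CSV ", path, " has no I_0 = 0 (no-inhibitor) control rows")
  cond <- assay_conditions(E_0 = E_0, timepoints = sort(unique(records$time_s)),
                           S = S, K_m = K_m)
  titration_dataset(records, cond, provenance = paste0("file: ", path))
}

#' Write a titration dataset to the tidy rates CSV contract
#'
#' @param data A [titration_dataset()].
#' @param path Output CSV path.
#' @param conc_unit Unit for the `inhibitor_conc` column on disk.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(data, path, conc_unit = "M") {
  stopifnot(inherits(data, "titration_dataset"))
  fac <- .conc_factor(conc_unit)
  out <- data.frame(
    time_s = formatC(data$time_s, digits = 15, format = "g"),
    inhibitor_conc = formatC(data$I0 / fac, digits = 15, format = "g"),
    rate = formatC(data$rate, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read one progress trace as CSV (`time_s`, `fluorescence_au`)
#'
#' @param trace A [progress_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [progress_trace()] (read).
#' @export
write_progress_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "progress_trace"))
  out <- data.frame(
    time_s = formatC(trace$times, digits = 15, format = "g"),
    fluorescence_au = formatC(trace$signal, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_progress_trace_csv
#' @param well_id,substrate_conc,signal_per_product Metadata attached to
#'   the trace on read (not stored in the CSV).
#' @export
read_progress_trace_csv <- function(path, well_id = basename(path),
                                    substrate_conc = NA_real_,
                                    signal_per_product = NA_real_) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "fluorescence_au") %in% names(df)))
    stop("trace CSV ", path, " must have columns time_s, fluorescence_au")
  progress_trace(as.numeric(df$time_s), as.numeric(df$fluorescence_au),
                 well_id = well_id, substrate_conc = substrate_conc,
                 signal_per_product = signal_per_product)
}

#' Read a JSON run configuration
#'
#' The run config is a single JSON object; see [run_pipeline()] for the
#' fields each mode understands.  Concentration fields must come with the
#' unit declared via the `conc_unit` key (applying to `inhibitor_conc`
#' columns of referenced CSVs); scalar concentrations inside the config
#' itself are mol/L.
#'
#' @param path JSON file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
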