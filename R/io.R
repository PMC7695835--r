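# CSV schemas are fixed and validated strictly: exact headers, '.' decimal
# separator, concentrations in molar, times in minutes. Numbers are written
# with 10 significant digits so a write -> read -> write cycle is
# byte-identical.

TRACE_COLUMNS <- c("well", "time_min", "tracer_conc_M", "competitor_conc_M",
                   "signal", "is_nsb")
DOSE_COLUMNS <- c("well", "conc_M", "raw_signal", "reference")
STABILITY_COLUMNS <- c("time_min", "pct_remaining", "matrix",
                       "protein_mg_per_ul")

check_columns <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[expected]
}

check_numeric_col <- function(df, cols, what) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA" &
                   df[[cl]] != "")
    if (length(bad))
      stop(sprintf("%s: column '%s' is not numeric at row(s) %s", what, cl,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    df[[cl]] <- v
  }
  df
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  out
}

write_schema_csv <- function(df, path, numeric_cols) {
  out <- df
  for (cl in numeric_cols) out[[cl]] <- fmt_num(df[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write kinetic-trace tables
#'
#' Long-format CSV of binding time courses with the exact header
#' `well,time_min,tracer_conc_M,competitor_conc_M,signal,is_nsb`.
#' Schema violations are reported with the offending column and row
#' numbers. `read_trace_table()` warns when the plate lacks an `I = 0`
#' control well (competition fitting requires one).
#'
#' @param path CSV file path.
#' @return `read_trace_table()`: a validated data frame;
#'   `write_trace_table()`: `path`, invisibly.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_columns(df, TRACE_COLUMNS, "trace table")
  df <- check_numeric_col(df, c("time_min", "tracer_conc_M",
                                "competitor_conc_M", "signal", "is_nsb"),
                          "trace table")
  if (!any(df$competitor_conc_M == 0 & df$is_nsb == 0))
    warning("trace table has no competitor-free (I = 0) control well",
            call. = FALSE)
  df
}

#' @rdname read_trace_table
#' @param df Data frame in the trace-table schema.
#' @export
write_trace_table <- function(df, path) {
  df <- check_columns(df, TRACE_COLUMNS, "trace table")
  write_schema_csv(df, path, setdiff(TRACE_COLUMNS, "well"))
}

#' Convert a trace table to kinetic traces
#'
#' Splits the non-NSB rows of a trace table into [kinetic_trace()]
#' objects, one per well.
#'
#' @param df A data frame from [read_trace_table()].
#' @return A list of [kinetic_trace()] objects.
#' @export
traces_from_table <- function(df) {
  df <- df[df$is_nsb == 0, ]
  lapply(split(df, df$well), function(w) {
    w <- w[order(w$time_min), ]
    kinetic_trace(w$time_min, w$signal, L = w$tracer_conc_M[1],
                  I = w$competitor_conc_M[1], well = w$well[1])
  })
}

#' Subtract the nonspecific-binding baseline from a trace table
#'
#' Specific binding is total signal minus the nonspecific component
#' measured in wells containing a saturating concentration of
#' unlabelled antagonist (`is_nsb = 1`). The mean NSB signal is
#' computed per tracer concentration and subtracted from all matching
#' non-NSB wells; NSB rows are then dropped.
#'
#' @param df A trace-table data frame containing NSB wells.
#' @return The table with `signal` NSB-corrected and NSB rows removed;
#'   attribute `nsb_level` records the per-tracer-concentration
#'   baselines.
#' @export
subtract_nsb <- function(df) {
  df <- check_columns(df, TRACE_COLUMNS, "trace table")
  if (!any(df$is_nsb == 1))
    stop("no NSB wells (is_nsb = 1) in table", call. = FALSE)
  nsb_arr <- tapply(df$signal[df$is_nsb == 1],
                    df$tracer_conc_M[df$is_nsb == 1], mean)
  nsb <- stats::setNames(as.numeric(nsb_arr), names(nsb_arr))
  out <- df[df$is_nsb == 0, ]
  out$signal <- out$signal - unname(nsb[as.character(out$tracer_conc_M)])
  rownames(out) <- NULL
  attr(out, "nsb_level") <- nsb
  out
}

#' Read and write dose-response tables
#'
#' CSV with the exact header `well,conc_M,raw_signal,reference`, where
#' `reference` is `none`, `ref_max` or `ref_min`; each plate must carry
#' at least one `ref_max` and one `ref_min` well to anchor
#' normalisation.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_columns(df, DOSE_COLUMNS, "dose-response table")
  df <- check_numeric_col(df, c("conc_M", "raw_signal"),
                          "dose-response table")
  bad <- which(!df$reference %in% c("none", "ref_max", "ref_min"))
  if (length(bad))
    stop(sprintf("dose-response table: invalid 'reference' at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (!any(df$reference == "ref_max") || !any(df$reference == "ref_min"))
    stop("dose-response table needs at least one ref_max and one ref_min well",
         call. = FALSE)
  df
}

#' @rdname read_dose_table
#' @param df Data frame in the dose-response schema.
#' @export
write_dose_table <- function(df, path) {
  df <- check_columns(df, DOSE_COLUMNS, "dose-response table")
  write_schema_csv(df, path, c("conc_M", "raw_signal"))
}

#' Read and write stability (depletion) tables
#'
#' CSV with the exact header
#' `time_min,pct_remaining,matrix,protein_mg_per_ul`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_stability_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_columns(df, STABILITY_COLUMNS, "stability table")
  check_numeric_col(df, c("time_min", "pct_remaining", "protein_mg_per_ul"),
                    "stability table")
}

#' @rdname read_stability_table
#' @param df Data frame in the stability schema.
#' @export
write_stability_table <- function(df, path) {
  df <- check_columns(df, STABILITY_COLUMNS, "stability table")
  write_schema_csv(df, path, c("time_min", "pct_remaining",
                               "protein_mg_per_ul"))
}

#' Serialise a fit result to JSON
#'
#' Writes a `ligandkin_fit` (or any named list of scalars/vectors) as a
#' JSON report; numbers are written at full precision.
#'
#' @param fit A `ligandkin_fit` or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rec <- if (inherits(fit, "ligandkin_fit")) {
    keep <- c("model", "params", "se", "ssr", "dof", "converged",
              "n_points", "ambiguous", "Ki", "pKi", "se_pKi", "RT")
    fit[intersect(keep, names(fit))]
  } else fit
  # named atomic vectors must become objects, not nameless arrays
  rec <- lapply(rec, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
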