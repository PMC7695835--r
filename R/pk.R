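#' A compound-depletion time series
#'
#' Percent of compound remaining versus incubation time, as measured in
#' a substrate-depletion stability assay (liver microsomes, plasma or
#' buffer).
#'
#' @param times Incubation times (min), ascending, >= 0.
#' @param pct_remaining Percent of the `t = 0` amount remaining; values
#'   slightly above 100 are tolerated (noise) but the `t = 0` point must
#'   lie within 90-110%.
#' @param matrix One of `"microsome"`, `"plasma"`, `"buffer"`.
#' @param protein_conc Microsomal protein concentration (mg protein per
#'   microlitre); required for intrinsic-clearance scaling, `NA`
#'   otherwise.
#' @return An object of class `depletion_series`.
#' @export
depletion_series <- function(times, pct_remaining,
                             matrix = c("microsome", "plasma", "buffer"),
                             protein_conc = NA_real_) {
  matrix <- match.arg(matrix)
  stopifnot(length(times) == length(pct_remaining))
  check_nonnegative(times = times)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(times == 0)) {
    p0 <- pct_remaining[times == 0]
    if (p0 < 90 || p0 > 110)
      stop("pct_remaining at t = 0 outside the 90-110% sanity band",
           call. = FALSE)
  }
  structure(list(times = times, pct_remaining = pct_remaining,
                 matrix = matrix, protein_conc = protein_conc),
            class = "depletion_series")
}

#' First-order half-life from a depletion series
#'
#' Regresses `ln(percent remaining)` on time; the slope `k` is the
#' first-order depletion rate and `t1/2 = -ln(2)/k`. All points enter
#' the regression (the `t = 0` point is not forced to 100%).
#' Nonpositive percentages cannot be log-transformed and are excluded
#' with a warning. When the slope is nonnegative the compound is not
#' measurably depleted: the half-life is reported as `Inf` with
#' `stable = TRUE`.
#'
#' @param series A [depletion_series()] object.
#' @return A list with `k` (min^-1, slope of the log-linear fit),
#'   `t_half` (min), `stable` flag and the underlying `lm` fit.
#' @examples
#' s <- depletion_series(c(0, 120), c(100, 90), matrix = "plasma")
#' halflife_from_depletion(s)$t_half   # 789.3 min, i.e. > 120 min
#' @export
halflife_from_depletion <- function(series) {
  stopifnot(inherits(series, "depletion_series"))
  keep <- series$pct_remaining > 0
  if (any(!keep))
    warning(sum(!keep), " nonpositive percent-remaining value(s) excluded",
            call. = FALSE)
  t <- series$times[keep]; p <- series$pct_remaining[keep]
  if (length(t) < 2)
    stop("need >= 2 time points with positive percent remaining",
         call. = FALSE)
  fit <- stats::lm(log(p) ~ t)
  k <- unname(stats::coef(fit)[2])
  stable <- k >= 0
  list(k = k,
       t_half = if (stable) Inf else -log(2) / k,
       stable = stable, fit = fit)
}

#' Intrinsic clearance from microsomal half-life
#'
#' `CLint = ln(2) / (t1/2 * protein_conc)` in microlitres per minute
#' per mg of microsomal protein. An infinite half-life (no measurable
#' depletion) gives a clearance of 0.
#'
#' @param t_half Depletion half-life (min), > 0 (may be `Inf`).
#' @param protein_conc Microsomal protein concentration (mg per
#'   microlitre), > 0.
#' @return Intrinsic clearance (ul/min/mg).
#' @examples
#' intrinsic_clearance(24, 1e-4)   # ~289 ul/min/mg
#' @export
intrinsic_clearance <- function(t_half, protein_conc) {
  check_positive(protein_conc = protein_conc)
  if (!all(t_half > 0)) stop("`t_half` must be positive", call. = FALSE)
  ifelse(is.infinite(t_half), 0, log(2) / (t_half * protein_conc))
}
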