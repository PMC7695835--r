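#' Fit tracer binding kinetics from association time courses
#'
#' Determines the tracer association rate constant `k1`, dissociation
#' rate constant `k2` and maximal signal `N` from tracer-only
#' (competitor-free) association traces at several tracer
#' concentrations. Two routes are computed:
#'
#' * a global fit of the mono-exponential association model
#'   `y(t) = N L k1 / (L k1 + k2) * (1 - exp(-(L k1 + k2) t))`
#'   with `k1`, `k2`, `N` shared across all traces (the reported
#'   parameters), and
#' * the classical observed-rate route: each trace is fitted
#'   individually for its plateau and observed rate `k_obs`, and
#'   `k_obs = k1 [L] + k2` is regressed on `[L]` (slope `k1`,
#'   intercept `k2`).
#'
#' @param traces List of [kinetic_trace()] objects, all with `I = 0`,
#'   covering at least 3 distinct tracer concentrations with at least 5
#'   time points each.
#' @param n_starts Number of log-spaced optimisation starts.
#'
#' @return A list with components `tracer` (a [tracer_kinetics()]
#'   object), `fit` (global-fit result with standard errors), `kobs`
#'   (per-trace observed rates) and `kobs_regression` (list with `k1`,
#'   `k2` from the linear route).
#' @export
fit_tracer_kinetics <- function(traces, n_starts = 5L) {
  if (any(vapply(traces, `[[`, 1, "I") != 0))
    stop("tracer-only traces must have I = 0", call. = FALSE)
  Ls <- vapply(traces, `[[`, 1, "L")
  if (length(unique(Ls)) < 3)
    stop("insufficient design: need >= 3 distinct tracer concentrations",
         call. = FALSE)
  if (any(vapply(traces, function(tr) length(tr$times), 1L) < 5))
    stop("insufficient design: each trace needs >= 5 time points",
         call. = FALSE)
  d <- stack_traces(traces)

  model <- function(par) {
    k1 <- 10^par[1]; k2 <- 10^par[2]; N <- 10^par[3]
    kobs <- d$L * k1 + k2
    N * d$L * k1 / kobs * (1 - exp(-kobs * d$t))
  }
  resid_fn <- function(par) d$y - model(par)

  # heuristics: plateau ~ max signal, kobs ~ 1 / (time to half-plateau)
  N0 <- max(d$y) * 1.5
  k20 <- 1 / max(median(d$t), 1e-6)
  k10 <- k20 / median(d$L)
  offsets <- seq(-2, 2, length.out = n_starts)
  starts <- cbind(log10(k10) + offsets, log10(k20) + offsets,
                  rep(log10(N0), n_starts))
  lower <- c(0, -6, log10(N0) - 4)
  upper <- c(15, 4, log10(N0) + 4)

  best <- multistart_nls(resid_fn, starts, lower, upper)
  ses <- nls_se(best, length(d$y))
  k1 <- 10^best$par[1]; k2 <- 10^best$par[2]; N <- 10^best$par[3]
  se_nat <- log(10) * c(k1, k2, N) * ses$se
  params <- c(k1 = k1, k2 = k2, N = N)
  names(se_nat) <- names(params)
  converged <- best$info %in% 1:3
  fit <- new_fit_result(
    model = "mono_exponential", params = params, se = se_nat,
    ssr = best$deviance, dof = ses$dof, converged = converged,
    n_points = length(d$y),
    ambiguous = flag_ambiguous(best$par, ses$se, lower, upper, converged))

  kobs_tab <- kobs_per_trace(traces)
  reg <- stats::lm(kobs ~ L, data = kobs_tab)
  kobs_reg <- list(k1 = unname(stats::coef(reg)[2]),
                   k2 = unname(stats::coef(reg)[1]),
                   fit = reg)

  list(tracer = tracer_kinetics(k1, k2, N), fit = fit,
       kobs = kobs_tab, kobs_regression = kobs_reg)
}

# Per-trace mono-exponential fit for (plateau, kobs).
kobs_per_trace <- function(traces) {
  rows <- lapply(traces, function(tr) {
    y <- tr$signal; t <- tr$times
    P0 <- max(y); kobs0 <- 1 / max(median(t[t > 0]), 1e-6)
    resid_fn <- function(par) y - 10^par[1] * (1 - exp(-10^par[2] * t))
    starts <- cbind(rep(log10(P0), 3), log10(kobs0) + c(-1, 0, 1))
    best <- multistart_nls(resid_fn, starts,
                           lower = c(log10(P0) - 4, -6),
                           upper = c(log10(P0) + 4, 4))
    data.frame(well = tr$well, L = tr$L,
               plateau = 10^best$par[1], kobs = 10^best$par[2])
  })
  do.call(rbind, rows)
}

#' Fit the full competition kinetics model to displacement traces
#'
#' Globally fits the closed-form two-ligand competition model
#' ([motulsky_mahan_occupancy()]) to tracer time courses acquired at
#' several competitor concentrations, estimating the competitor rate
#' constants `k3` and `k4` (and the shared maximal signal `N`) with the
#' tracer parameters `k1`, `k2` held fixed at their separately
#' determined values. Derived quantities: `Ki = k4/k3`,
#' `pKi = -log10(Ki)` and the residence time `RT = 1/k4`.
#'
#' A fit is flagged ambiguous when a parameter's standard error exceeds
#' ten times its estimate, when an estimate sits at an optimisation
#' bound, or when the optimiser fails to converge — the situations in
#' which a fast-dissociating competitor's rate constants are not
#' resolvable from the data and only its affinity is meaningful (see
#' [fit_competition_rapid()]).
#'
#' @param traces List of [kinetic_trace()] objects at >= 3 distinct
#'   competitor concentrations (an `I = 0` control is strongly
#'   recommended), all at one tracer concentration.
#' @param tracer A [tracer_kinetics()] object (fixed `k1`, `k2`).
#' @param n_starts Number of log-spaced optimisation starts.
#'
#' @return A `ligandkin_fit` with `model = "motulsky_mahan"`, estimates
#'   and standard errors for `k3`, `k4`, `N`, and fields `Ki`, `pKi`,
#'   `RT`, `ambiguous`.
#' @export
fit_competition_full <- function(traces, tracer, n_starts = 5L) {
  d <- check_competition_design(traces)
  model <- function(par) {
    k3 <- 10^par[1]; k4 <- 10^par[2]; N <- 10^par[3]
    cp <- structure(list(k3 = k3, k4 = k4, Ki = k4 / k3),
                    class = "competitor_kinetics")
    tr <- structure(list(k1 = tracer$k1, k2 = tracer$k2, N = N,
                         KD = tracer$KD), class = "tracer_kinetics")
    y <- numeric(length(d$t))
    for (i in unique(d$idx)) {
      sel <- d$idx == i
      y[sel] <- motulsky_mahan_occupancy(d$t[sel], tr, cp,
                                         L = d$L[sel][1], I = d$I[sel][1])
    }
    y
  }
  resid_fn <- function(par) d$y - model(par)

  Ki0 <- exp(mean(log(d$I[d$I > 0])))
  N0 <- guess_bmax(d, tracer)
  k4_starts <- 10^seq(-3, 2, length.out = n_starts)
  starts <- cbind(log10(k4_starts / Ki0), log10(k4_starts),
                  rep(log10(N0), n_starts))
  lower <- c(2, -6, log10(N0) - 4)
  upper <- c(14, 6, log10(N0) + 4)

  best <- multistart_nls(resid_fn, starts, lower, upper)
  ses <- nls_se(best, length(d$y))
  k3 <- 10^best$par[1]; k4 <- 10^best$par[2]; N <- 10^best$par[3]
  params <- c(k3 = k3, k4 = k4, N = N)
  se_nat <- log(10) * c(k3, k4, N) * ses$se
  names(se_nat) <- names(params)
  converged <- best$info %in% 1:3
  ambiguous <- flag_ambiguous(best$par, ses$se, lower, upper, converged)

  # delta method for pKi = log10(k3) - log10(k4), using the log-scale vcov
  se_pKi <- if (!is.null(ses$vcov))
    sqrt(ses$vcov[1, 1] + ses$vcov[2, 2] - 2 * ses$vcov[1, 2]) else NA_real_

  new_fit_result(
    model = "motulsky_mahan", params = params, se = se_nat,
    ssr = best$deviance, dof = ses$dof, converged = converged,
    n_points = length(d$y), ambiguous = ambiguous,
    extra = list(Ki = k4 / k3, pKi = log10(k3) - log10(k4),
                 se_pKi = se_pKi, RT = 1 / k4))
}

#' Fit the rapid-competitor-dissociation model to displacement traces
#'
#' Globally fits the mono-exponential limiting model
#' ([rapid_competition_occupancy()]), in which the competitor
#' equilibrates instantly with free receptor, so only its equilibrium
#' affinity `Ki` (plus the shared maximal signal `N`) is estimated.
#'
#' @inheritParams fit_competition_full
#' @return A `ligandkin_fit` with `model = "rapid_dissociation"`,
#'   estimates for `Ki`, `N`, and fields `Ki`, `pKi`, `ambiguous`.
#' @export
fit_competition_rapid <- function(traces, tracer, n_starts = 5L) {
  d <- check_competition_design(traces, min_conc = 2L)
  if (all(d$I == 0))
    stop("insufficient design: Ki is unidentifiable without I > 0 traces",
         call. = FALSE)
  model <- function(par) {
    Ki <- 10^par[1]; N <- 10^par[2]
    tr <- structure(list(k1 = tracer$k1, k2 = tracer$k2, N = N,
                         KD = tracer$KD), class = "tracer_kinetics")
    rho <- d$I / (Ki + d$I)
    kobs <- d$L * tracer$k1 * (1 - rho) + tracer$k2
    N * d$L * tracer$k1 * (1 - rho) / kobs * (1 - exp(-kobs * d$t))
  }
  resid_fn <- function(par) d$y - model(par)

  Ki0 <- exp(mean(log(d$I[d$I > 0])))
  N0 <- guess_bmax(d, tracer)
  offsets <- seq(-2, 2, length.out = n_starts)
  starts <- cbind(log10(Ki0) + offsets, rep(log10(N0), n_starts))
  lower <- c(-14, log10(N0) - 4)
  upper <- c(0, log10(N0) + 4)

  best <- multistart_nls(resid_fn, starts, lower, upper)
  ses <- nls_se(best, length(d$y))
  Ki <- 10^best$par[1]; N <- 10^best$par[2]
  params <- c(Ki = Ki, N = N)
  se_nat <- log(10) * c(Ki, N) * ses$se
  names(se_nat) <- names(params)
  converged <- best$info %in% 1:3

  new_fit_result(
    model = "rapid_dissociation", params = params, se = se_nat,
    ssr = best$deviance, dof = ses$dof, converged = converged,
    n_points = length(d$y),
    ambiguous = flag_ambiguous(best$par, ses$se, lower, upper, converged),
    extra = list(Ki = Ki, pKi = -log10(Ki), se_pKi = ses$se[1]))
}

check_competition_design <- function(traces, min_conc = 3L) {
  d <- stack_traces(traces)
  Is <- vapply(traces, `[[`, 1, "I")
  n_conc <- length(unique(Is))
  if (n_conc < min_conc)
    stop(sprintf(
      "insufficient design: need >= %d distinct competitor concentrations (got %d)",
      min_conc, n_conc), call. = FALSE)
  if (!any(Is == 0))
    stop("insufficient design: no competitor-free (I = 0) control trace",
         call. = FALSE)
  d
}

# Bmax guess from the I = 0 control plateau (or the overall maximum),
# corrected for fractional tracer occupancy at the plateau.
guess_bmax <- function(d, tracer) {
  top <- if (any(d$I == 0)) max(d$y[d$I == 0]) else max(d$y)
  L <- d$L[1]
  frac <- L * tracer$k1 / (L * tracer$k1 + tracer$k2)
  max(top / frac, 1e-12)
}

#' Compare nested fits with the extra-sum-of-squares F-test
#'
#' Partial F-test between a simpler model (fewer parameters, larger
#' residual degrees of freedom) and a more complex one fitted to the
#' same data:
#' \deqn{F = \frac{(SSR_s - SSR_c)/(df_s - df_c)}{SSR_c/df_c}}
#' with the p-value from the upper tail of `F(df_s - df_c, df_c)`. The
#' complex model is selected only when it fits significantly better
#' (`p < alpha`); a negative numerator (the complex model fitting no
#' better) clamps `F` to 0.
#'
#' @param simple,complex `ligandkin_fit` objects on the same data
#'   (`n_points` must match, `dof_simple > dof_complex`).
#' @param alpha Significance level for selecting the complex model.
#'
#' @return A list with `f_stat`, `p_value`, `df_num`, `df_den`,
#'   `selected` (model label) and `alpha`.
#' @export
compare_models <- function(simple, complex, alpha = 0.05) {
  stopifnot(inherits(simple, "ligandkin_fit"),
            inherits(complex, "ligandkin_fit"))
  if (simple$n_points != complex$n_points)
    stop("fits must be on the same data (n_points differ)", call. = FALSE)
  if (simple$dof <= complex$dof)
    stop("`simple` must have more residual degrees of freedom", call. = FALSE)
  df_num <- simple$dof - complex$dof
  df_den <- complex$dof
  f <- ((simple$ssr - complex$ssr) / df_num) / (complex$ssr / df_den)
  f <- max(f, 0)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  list(f_stat = f, p_value = p, df_num = df_num, df_den = df_den,
       selected = if (p < alpha) complex$model else simple$model,
       alpha = alpha)
}

#' Fit both competition models and select one by partial F-test
#'
#' Convenience wrapper: fits the rapid-dissociation (simple) and full
#' Motulsky-Mahan (complex) models to the same traces and applies
#' [compare_models()].
#'
#' @inheritParams fit_competition_full
#' @param alpha Significance level for the F-test.
#' @return A list with `full`, `rapid`, `comparison` and `selected`
#'   (the winning `ligandkin_fit`).
#' @export
fit_competition_auto <- function(traces, tracer, alpha = 0.05,
                                 n_starts = 5L) {
  rapid <- fit_competition_rapid(traces, tracer, n_starts = n_starts)
  full <- fit_competition_full(traces, tracer, n_starts = n_starts)
  cmp <- compare_models(rapid, full, alpha = alpha)
  list(full = full, rapid = rapid, comparison = cmp,
       selected = if (cmp$selected == "motulsky_mahan") full else rapid)
}
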