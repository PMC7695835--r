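#' Normalise raw signals to plate references
#'
#' Linear rescaling of raw plate signals so that the `reference_max`
#' wells map to 100% and the `reference_min` wells map to 0% (e.g.
#' forskolin-stimulated cAMP as the 100% reference for Gi-coupled
#' inhibition assays). Values are passed through unclamped, so signals
#' below the lower reference yield negative percentages — inverse
#' agonism shows up as a response below basal.
#'
#' @param raw Raw signal(s).
#' @param reference_max Signal that defines 100%.
#' @param reference_min Signal that defines 0%.
#' @param mode `"inhibition"` or `"stimulation"`; recorded as the
#'   `direction` attribute for downstream curve fitting (the linear map
#'   itself is identical — the mode states which biological reference
#'   was used for each anchor).
#'
#' @return Percentages with attribute `direction`.
#' @export
normalize_response <- function(raw, reference_max, reference_min,
                               mode = c("inhibition", "stimulation")) {
  mode <- match.arg(mode)
  if (!is.finite(reference_max) || !is.finite(reference_min) ||
      reference_max == reference_min)
    stop("degenerate references: reference_max must differ from reference_min",
         call. = FALSE)
  out <- 100 * (raw - reference_min) / (reference_max - reference_min)
  attr(out, "direction") <- mode
  out
}

#' Fit a three-parameter logistic dose-response curve
#'
#' Fits `Y = bottom + (top - bottom) / (1 + 10^((logEC50 - logX) * s))`
#' with the Hill slope fixed at unity (`s = +1` for stimulation, `s = -1`
#' for inhibition), the standard three-parameter logistic used for
#' IC50/EC50 estimation. A free-slope four-parameter variant is
#' available via `hill = NULL`.
#'
#' @param conc Molar concentrations (> 0), at least 5 distinct values.
#' @param response Responses (normalised or raw; the fit is
#'   scale-equivariant).
#' @param direction `"inhibition"` (response falls with concentration)
#'   or `"stimulation"`.
#' @param hill Fixed Hill slope magnitude (default 1). `NULL` frees the
#'   slope (4-parameter logistic).
#'
#' @return An object of class `dose_response_fit` with fields `top`,
#'   `bottom`, `logEC50`, `pEC50` (`-logEC50`), `span`, `hill`,
#'   standard errors, `ssr`, `dof` and diagnostic `flags`
#'   (`wide_ci`: concentration span under one log unit or midpoint
#'   outside the tested range; `poor_fit`: systematic residual runs).
#' @export
fit_logistic3 <- function(conc, response,
                          direction = c("inhibition", "stimulation"),
                          hill = 1) {
  direction <- match.arg(direction)
  stopifnot(length(conc) == length(response))
  check_positive(conc = conc)
  if (length(unique(conc)) < 5)
    stop("need >= 5 distinct concentrations", call. = FALSE)
  lx <- log10(conc)
  s_sign <- if (direction == "stimulation") 1 else -1
  free_hill <- is.null(hill)

  model <- function(par) {
    top <- par[1]; bottom <- par[2]; logec50 <- par[3]
    h <- if (free_hill) exp(par[4]) else hill
    bottom + (top - bottom) / (1 + 10^((logec50 - lx) * s_sign * h))
  }
  resid_fn <- function(par) response - model(par)

  top0 <- max(response); bot0 <- min(response)
  grid <- seq(min(lx), max(lx), length.out = 5)
  starts <- unname(cbind(top0, bot0, grid, if (free_hill) 0 else NULL))
  lower <- c(bot0 - 2 * (top0 - bot0 + 1), bot0 - 2 * (top0 - bot0 + 1),
             min(lx) - 6, if (free_hill) log(0.1) else NULL)
  upper <- c(top0 + 2 * (top0 - bot0 + 1), top0 + 2 * (top0 - bot0 + 1),
             max(lx) + 6, if (free_hill) log(10) else NULL)
  best <- multistart_nls(resid_fn, starts, lower, upper)
  ses <- nls_se(best, length(response))

  top <- unname(best$par[1]); bottom <- unname(best$par[2])
  logec50 <- unname(best$par[3])
  h <- if (free_hill) exp(unname(best$par[4])) else hill
  fitted <- model(best$par)
  flags <- list(
    wide_ci = diff(range(lx)) < 1 ||
      logec50 < min(lx) || logec50 > max(lx),
    poor_fit = runs_test_p(response - fitted) < 0.01)

  params <- c(top = top, bottom = bottom, logEC50 = logec50)
  se <- c(top = ses$se[1], bottom = ses$se[2], logEC50 = ses$se[3])
  structure(list(
    conc = conc, response = response, direction = direction,
    top = top, bottom = bottom, logEC50 = logec50,
    pEC50 = -logec50, span = abs(top - bottom), hill = h,
    params = params, se = se, ssr = best$deviance, dof = ses$dof,
    converged = best$info %in% 1:3, flags = flags, fitted = fitted),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lab <- if (x$direction == "inhibition") "pIC50" else "pEC50"
  cat(sprintf("3PL fit (%s): %s = %.3f, top = %.3g, bottom = %.3g, span = %.3g\n",
              x$direction, lab, x$pEC50, x$top, x$bottom, x$span))
  if (x$flags$wide_ci) cat("  flag: midpoint/plateaus poorly constrained\n")
  if (x$flags$poor_fit) cat("  flag: systematic lack of fit\n")
  invisible(x)
}

#' Dose ratio from two fitted potencies
#'
#' `DR = 10^(pEC50_control - pEC50_antagonist)`: the fold rightward
#' shift of the agonist curve caused by an antagonist. Ratios at or
#' below 1 (no shift) are flagged via the `no_shift` attribute and a
#' warning.
#'
#' @param pEC50_control Agonist potency alone (-log10 M).
#' @param pEC50_antagonist Agonist potency in the presence of
#'   antagonist.
#' @return Dose ratio(s) with logical attribute `no_shift`.
#' @export
dose_ratio <- function(pEC50_control, pEC50_antagonist) {
  stopifnot(is.finite(pEC50_control), is.finite(pEC50_antagonist))
  dr <- 10^(pEC50_control - pEC50_antagonist)
  ns <- dr <= 1
  if (any(ns)) warning("dose ratio <= 1: no rightward shift", call. = FALSE)
  attr(dr, "no_shift") <- ns
  dr
}

#' Schild regression for competitive antagonism
#'
#' Regresses `log10(DR - 1)` on `log10([B])` over antagonist
#' concentrations `[B]`. The x-intercept gives `pA2`; a slope of 1 is
#' the signature of simple competitive antagonism (Gaddum:
#' `DR = 1 + [B]/KB`), and refitting with the slope constrained to
#' unity turns the intercept into the antagonist affinity `pKB`. Dose
#' ratios at or below 1 carry no shift information and are excluded
#' with a warning.
#'
#' @param antagonist_concs Antagonist concentrations (M), > 0.
#' @param dose_ratios Dose ratios at each concentration.
#' @return An object of class `schild_result` with fields `slope`,
#'   `slope_se`, `pA2`, `pKB`, the points used, and the unconstrained
#'   `lm` fit.
#' @export
schild_regression <- function(antagonist_concs, dose_ratios) {
  stopifnot(length(antagonist_concs) == length(dose_ratios))
  check_positive(antagonist_concs = antagonist_concs)
  usable <- dose_ratios > 1
  if (any(!usable))
    warning(sum(!usable), " point(s) with DR <= 1 excluded", call. = FALSE)
  if (sum(usable) < 2)
    stop("need >= 2 antagonist concentrations with DR > 1", call. = FALSE)
  x <- log10(antagonist_concs[usable])
  y <- log10(dose_ratios[usable] - 1)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[2])
  pA2 <- unname(cf[1] / cf[2])        # -(x-intercept)
  pKB <- mean(y - x)                  # slope fixed at unity
  structure(list(
    antagonist_concs = antagonist_concs[usable],
    dose_ratios = dose_ratios[usable],
    slope = slope,
    slope_se = unname(suppressWarnings(summary(fit))$coefficients[2, 2]),
    pA2 = pA2, pKB = pKB, fit = fit),
    class = "schild_result")
}

#' @export
print.schild_result <- function(x, ...) {
  cat(sprintf("Schild regression (%d points): slope = %.3f +/- %.3f, pA2 = %.3f, pKB = %.3f\n",
              length(x$dose_ratios), x$slope, x$slope_se, x$pA2, x$pKB))
  invisible(x)
}

#' Fit one-site saturation binding
#'
#' Fits the hyperbola `B = Bmax [L] / (KD + [L])` to specific binding
#' versus ligand concentration.
#'
#' @param L Ligand concentrations (M), >= 0, at least 5 spanning `KD`.
#' @param specific_signal Specific binding at each concentration.
#' @return A list with `KD`, `Bmax`, standard errors, `ssr`, `dof`, and
#'   `flags$top_unresolved` (TRUE when the tested range does not reach
#'   the fitted `KD`, so the plateau is extrapolated).
#' @export
fit_saturation <- function(L, specific_signal) {
  stopifnot(length(L) == length(specific_signal))
  check_nonnegative(L = L)
  if (length(unique(L)) < 5)
    stop("need >= 5 concentrations", call. = FALSE)
  model <- function(par) {
    KD <- 10^par[1]; Bmax <- 10^par[2]
    Bmax * L / (KD + L)
  }
  resid_fn <- function(par) specific_signal - model(par)
  Bmax0 <- max(specific_signal) * 1.2
  Lpos <- L[L > 0]
  grid <- log10(range(Lpos)) + c(-1, 1)
  starts <- cbind(seq(grid[1], grid[2], length.out = 5), log10(Bmax0))
  best <- multistart_nls(resid_fn, starts,
                         lower = c(grid[1] - 6, log10(Bmax0) - 4),
                         upper = c(grid[2] + 6, log10(Bmax0) + 4))
  ses <- nls_se(best, length(L))
  KD <- 10^best$par[1]; Bmax <- 10^best$par[2]
  se_nat <- log(10) * c(KD, Bmax) * ses$se
  list(KD = KD, Bmax = Bmax,
       se = c(KD = se_nat[1], Bmax = se_nat[2]),
       ssr = best$deviance, dof = ses$dof,
       converged = best$info %in% 1:3,
       flags = list(top_unresolved = max(L) < KD))
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + [L]/KD)`: corrects a competition IC50 for the
#' occupancy of the labelled tracer present at concentration `[L]` with
#' dissociation constant `KD`.
#'
#' @param IC50 Half-maximal inhibitory concentration (M), > 0.
#' @param L Tracer concentration (M), > 0.
#' @param KD Tracer equilibrium dissociation constant (M), > 0.
#' @return A list with `Ki` (M) and `pKi` (`-log10(Ki)`).
#' @examples
#' cheng_prusoff(3.226e-7, L = 100e-9, KD = 102e-9)$pKi  # 6.79
#' @export
cheng_prusoff <- function(IC50, L, KD) {
  check_positive(IC50 = IC50, L = L, KD = KD)
  Ki <- IC50 / (1 + L / KD)
  list(Ki = Ki, pKi = -log10(Ki))
}

#' One-site competition binding fit with Cheng-Prusoff conversion
#'
#' Fits the inhibition of tracer binding by an unlabelled compound with
#' a three-parameter logistic (Hill slope fixed at 1, the one-site
#' competitive case) and converts the fitted IC50 to `Ki` via
#' [cheng_prusoff()].
#'
#' @param conc Unlabelled-compound concentrations (M), > 0.
#' @param bound Bound tracer signal at each concentration.
#' @param L Tracer concentration (M).
#' @param KD Tracer equilibrium dissociation constant (M).
#' @return A list with `IC50`, `Ki`, `pKi`, the underlying
#'   `dose_response_fit`, and `flags` (`no_inhibition`: the curve is
#'   flat relative to residual noise; `lack_of_fit`: systematic
#'   residual runs, e.g. a non-unit Hill slope).
#' @export
one_site_competition_fit <- function(conc, bound, L, KD) {
  fit <- fit_logistic3(conc, bound, direction = "inhibition", hill = 1)
  resid_sd <- sqrt(fit$ssr / fit$dof)
  flags <- list(
    no_inhibition = fit$span < 4 * max(resid_sd, 1e-12),
    lack_of_fit = fit$flags$poor_fit)
  if (flags$no_inhibition)
    warning("no concentration-dependent inhibition detected", call. = FALSE)
  cp <- cheng_prusoff(10^fit$logEC50, L, KD)
  list(IC50 = 10^fit$logEC50, Ki = cp$Ki, pKi = cp$pKi,
       fit = fit, flags = flags)
}

#' Welch test for a contrast between two fitted parameters
#'
#' Two-sample Welch t-test computed from summary statistics (estimate,
#' standard error, residual degrees of freedom), for comparing fit
#' parameters across independent datasets. Degrees of freedom by
#' Welch-Satterthwaite.
#'
#' @param est1,est2 Parameter estimates.
#' @param se1,se2 Their standard errors.
#' @param df1,df2 Residual degrees of freedom of each fit.
#' @return A list with `t`, `df`, `p_value`, `difference`.
#' @export
welch_test <- function(est1, se1, df1, est2, se2, df2) {
  v1 <- se1^2; v2 <- se2^2
  t <- (est1 - est2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / df1 + v2^2 / df2)
  list(t = t, df = df,
       p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       difference = est1 - est2)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation);
# small p indicates systematic misfit.
runs_test_p <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 5) return(1)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}
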