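# Shared nonlinear least-squares plumbing. All kinetic/affinity parameters
# are optimised as log10 values so positivity holds by construction; each
# fit is restarted from several log-spaced initial guesses and the lowest
# sum of squared residuals wins.

multistart_nls <- function(resid_fn, starts, lower, upper,
                           maxiter = 300L) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fn,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  best
}

# Standard errors (log10 scale) and covariance from the converged fit.
# The normal matrix is inverted by SVD pseudo-inverse: at a zero-residual
# optimum a Jacobian column can underflow to exact zeros, and the proper
# limit there is zero uncertainty, not a failed solve.
nls_se <- function(fit, n_points) {
  p <- length(fit$par)
  dof <- n_points - p
  out <- list(se = rep(NA_real_, p), vcov = NULL, dof = dof)
  s2 <- fit$deviance / dof
  sv <- tryCatch(svd(fit$hessian), error = function(e) NULL)
  if (is.null(sv)) return(out)
  pos <- sv$d > max(sv$d) * p * .Machine$double.eps
  if (!any(pos)) return(out)
  cv <- s2 * sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  d <- diag(cv)
  if (all(is.finite(d)) && all(d >= 0)) {
    out$se <- sqrt(d)
    out$vcov <- cv
  }
  out
}

# Prism-style "ambiguous" heuristic: a parameter is unresolved when its
# standard error dwarfs the estimate, when it is pinned at an optimisation
# bound, or when the optimiser did not converge. `se_log` is on the log10
# scale, so se_log > 10 / ln(10) corresponds to SE > 10x the estimate.
flag_ambiguous <- function(par, se_log, lower, upper, converged) {
  near_bound <- (par - lower) < log10(1.01) | (upper - par) < log10(1.01)
  big_se <- !is.finite(se_log) | se_log > 10 / log(10)
  !converged || any(near_bound) || any(big_se)
}

# Convert a log10-scale estimate and SE to the natural scale
# (delta method: SE_x = ln(10) * x * SE_log10x).
log10_to_natural <- function(par, se_log) {
  est <- 10^par
  list(est = est, se = log(10) * est * se_log)
}

new_fit_result <- function(model, params, se, ssr, dof, converged,
                           n_points, ambiguous = FALSE, extra = list()) {
  stopifnot(ssr >= 0, dof > 0)
  structure(
    c(list(model = model, params = params, se = se, ssr = ssr, dof = dof,
           converged = converged, n_points = n_points,
           ambiguous = ambiguous),
      extra),
    class = "ligandkin_fit")
}

#' @export
print.ligandkin_fit <- function(x, ...) {
  cat(sprintf("Model: %s  (SSR = %.4g, dof = %d, %s%s)\n", x$model, x$ssr,
              x$dof, if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$ambiguous)) ", AMBIGUOUS" else ""))
  tab <- data.frame(estimate = x$params,
                    std.error = x$se[names(x$params)])
  print(format(tab, digits = 4))
  invisible(x)
}

# Stack a list of kinetic_trace objects into aligned vectors.
stack_traces <- function(traces) {
  stopifnot(length(traces) > 0,
            all(vapply(traces, inherits, TRUE, "kinetic_trace")))
  list(t = unlist(lapply(traces, `[[`, "times")),
       y = unlist(lapply(traces, `[[`, "signal")),
       L = unlist(lapply(traces, function(tr) rep(tr$L, length(tr$times)))),
       I = unlist(lapply(traces, function(tr) rep(tr$I, length(tr$times)))),
       idx = rep(seq_along(traces),
                 vapply(traces, function(tr) length(tr$times), 1L)))
}
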