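#' Numerical solution of the two-ligand mass-action system
#'
#' Integrates the coupled ordinary differential equations
#' \deqn{dRL/dt = k_1 [L] (N - RL - RI) - k_2 RL}
#' \deqn{dRI/dt = k_3 [I] (N - RL - RI) - k_4 RI}
#' from empty receptor at `t = 0`, with both ligands in excess (receptor
#' conservation `R = N - RL - RI`, no ligand depletion). This is the
#' same mass-action scheme whose closed-form solution is
#' [motulsky_mahan_occupancy()]; the numerical route exists as an
#' independent cross-check and for exploratory extensions.
#'
#' @param t Output times (min), nonnegative; need not include 0.
#' @param tracer A [tracer_kinetics()] object.
#' @param comp A [competitor_kinetics()] object.
#' @param L Tracer concentration (M), > 0.
#' @param I Competitor concentration (M), >= 0.
#' @param rtol,atol Integration tolerances passed to [deSolve::lsoda()].
#'
#' @return Numeric vector of tracer-bound signal `RL` at each `t`.
#' @export
simulate_competition_ode <- function(t, tracer, comp, L, I,
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(is.numeric(t), all(t >= 0))
  check_positive(L = L)
  check_nonnegative(I = I)
  times <- sort(unique(c(0, t)))
  deriv <- function(time, y, parms) {
    free <- tracer$N - y[1] - y[2]
    list(c(tracer$k1 * L * free - tracer$k2 * y[1],
           comp$k3 * I * free - comp$k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(RL = 0, RI = 0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  sol[match(t, sol[, "time"]), "RL"]
}
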