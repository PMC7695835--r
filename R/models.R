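#' Tracer kinetic parameters
#'
#' Bundles the rate constants of the labelled tracer ligand (e.g. a
#' fluorescent antagonist read out by BRET) together with the maximal
#' specific signal. The equilibrium dissociation constant is derived as
#' `k2 / k1`.
#'
#' @param k1 Tracer association rate constant (M^-1 min^-1), > 0.
#' @param k2 Tracer dissociation rate constant (min^-1), > 0.
#' @param N Maximal specific signal (Bmax, arbitrary signal units), > 0.
#'
#' @return An object of class `tracer_kinetics` with fields `k1`, `k2`,
#'   `N` and the derived `KD` (M).
#' @examples
#' tr <- tracer_kinetics(k1 = 2.86e7, k2 = 0.4397, N = 1)
#' tr$KD   # k2 / k1
#' @export
tracer_kinetics <- function(k1, k2, N = 1) {
  check_positive(k1 = k1, k2 = k2, N = N)
  structure(list(k1 = k1, k2 = k2, N = N, KD = k2 / k1),
            class = "tracer_kinetics")
}

#' Competitor kinetic parameters
#'
#' Rate constants of the unlabelled competitor; `Ki` is derived as
#' `k4 / k3`.
#'
#' @param k3 Competitor association rate constant (M^-1 min^-1), > 0.
#' @param k4 Competitor dissociation rate constant (min^-1), > 0.
#'
#' @return An object of class `competitor_kinetics` with fields `k3`,
#'   `k4` and derived `Ki` (M).
#' @export
competitor_kinetics <- function(k3, k4) {
  check_positive(k3 = k3, k4 = k4)
  structure(list(k3 = k3, k4 = k4, Ki = k4 / k3),
            class = "competitor_kinetics")
}

#' Rapidly equilibrating competitor
#'
#' A competitor whose dissociation is too fast for its rate constants to
#' be resolved; it is characterised by its equilibrium dissociation
#' constant only.
#'
#' @param Ki Equilibrium dissociation constant (M), > 0.
#' @return An object of class `rapid_competitor`.
#' @export
rapid_competitor <- function(Ki) {
  check_positive(Ki = Ki)
  structure(list(Ki = Ki), class = "rapid_competitor")
}

#' @export
print.tracer_kinetics <- function(x, ...) {
  cat(sprintf("Tracer kinetics: k1 = %.4g M^-1 min^-1, k2 = %.4g min^-1, KD = %.4g M, N = %.4g\n",
              x$k1, x$k2, x$KD, x$N))
  invisible(x)
}

#' @export
print.competitor_kinetics <- function(x, ...) {
  cat(sprintf("Competitor kinetics: k3 = %.4g M^-1 min^-1, k4 = %.4g min^-1, Ki = %.4g M\n",
              x$k3, x$k4, x$Ki))
  invisible(x)
}

#' Observed fast/slow rates of the two-ligand competition system
#'
#' The mass-action system for one tracer and one competitor binding a
#' common site relaxes with two observed exponential rates. `KA` and
#' `KB` are the pseudo-first-order rates of tracer and competitor alone;
#' `KF` and `KS` are the fast and slow eigenrates of the coupled system:
#' \deqn{K_F, K_S = \tfrac12\{K_A + K_B \pm \sqrt{(K_A-K_B)^2 + 4[L][I]k_1 k_3}\}}
#'
#' @param tracer A [tracer_kinetics()] object.
#' @param comp A [competitor_kinetics()] object.
#' @param L Tracer concentration (M), > 0.
#' @param I Competitor concentration (M), >= 0.
#'
#' @return A list with `KA`, `KB`, `KF`, `KS` (all min^-1), `KF >= KS`.
#' @export
eigen_rates <- function(tracer, comp, L, I) {
  check_positive(L = L)
  check_nonnegative(I = I)
  KA <- L * tracer$k1 + tracer$k2
  KB <- I * comp$k3 + comp$k4
  disc <- sqrt((KA - KB)^2 + 4 * L * I * tracer$k1 * comp$k3)
  list(KA = KA, KB = KB,
       KF = 0.5 * (KA + KB + disc),
       KS = 0.5 * (KA + KB - disc))
}

#' Tracer occupancy under simultaneous competition (Motulsky-Mahan)
#'
#' Closed-form specific binding of a labelled tracer at time `t` when an
#' unlabelled competitor binds the same site out of equilibrium
#' ("kinetics of competitive binding"):
#' \deqn{[RL]_t = \frac{N[L]k_1}{K_F-K_S}\left[\frac{k_4(K_F-K_S)}{K_F K_S}
#'   - \frac{k_4-K_S}{K_S}e^{-K_S t} + \frac{k_4-K_F}{K_F}e^{-K_F t}\right]}
#' Both ligands are assumed in excess over receptor (no depletion) and
#' binding starts from empty receptor at `t = 0`.
#'
#' When the two eigenrates coincide (`I = 0` can make `KB == KA`), the
#' printed expression is singular; the analytic repeated-root limit is
#' used whenever `|KF - KS| / KF < 1e-9`.
#'
#' @param t Time (min), >= 0; vectorised.
#' @param tracer A [tracer_kinetics()] object.
#' @param comp A [competitor_kinetics()] object.
#' @param L Tracer concentration (M), > 0.
#' @param I Competitor concentration (M), >= 0.
#'
#' @return Specific-binding signal at each `t`; 0 at `t = 0`, bounded
#'   above by `tracer$N`.
#' @examples
#' tr <- tracer_kinetics(2.86e7, 0.4397)
#' cp <- competitor_kinetics(3.25e8, 0.0248)
#' motulsky_mahan_occupancy(c(0, 5, 30), tr, cp, L = 5e-9, I = 1e-8)
#' @export
motulsky_mahan_occupancy <- function(t, tracer, comp, L, I) {
  stopifnot(is.numeric(t), all(t >= 0))
  check_positive(L = L)
  check_nonnegative(I = I)
  er <- eigen_rates(tracer, comp, L, I)
  KF <- er$KF; KS <- er$KS
  k1 <- tracer$k1; k4 <- comp$k4; N <- tracer$N
  if ((KF - KS) / KF < 1e-9) {
    # repeated-root limit: bracket/(KF-KS) -> d/dK[(k4-K)/K e^{-Kt}]
    K <- KF
    return(N * L * k1 *
             (k4 / K^2 - exp(-K * t) * (k4 / K^2 + t * (k4 - K) / K)))
  }
  N * L * k1 / (KF - KS) *
    (k4 * (KF - KS) / (KF * KS) -
       (k4 - KS) / KS * exp(-KS * t) +
       (k4 - KF) / KF * exp(-KF * t))
}

#' Fractional receptor occupancy by a rapidly equilibrating competitor
#'
#' The hyperbolic occupancy of receptors not bound by the tracer,
#' `rho = I / (Ki + I)`.
#'
#' @param I Competitor concentration (M), >= 0; vectorised.
#' @param Ki Competitor equilibrium dissociation constant (M), > 0.
#' @return Fraction in `[0, 1)`.
#' @export
fractional_occupancy <- function(I, Ki) {
  check_positive(Ki = Ki)
  check_nonnegative(I = I)
  I / (Ki + I)
}

#' Observed tracer association rate in the presence of competitor
#'
#' `k_obs = [L] k1 (1 - rho) + k2`: the competitor pre-occupies a
#' fraction `rho` of free receptor, slowing the apparent tracer on-rate
#' but never below the off-rate `k2`.
#'
#' @param L Tracer concentration (M), > 0.
#' @param tracer A [tracer_kinetics()] object.
#' @param rho Fractional occupancy by the competitor, in `[0, 1)`.
#' @return Observed rate (min^-1), >= `tracer$k2`.
#' @export
observed_association_rate <- function(L, tracer, rho) {
  check_positive(L = L)
  if (any(rho < 0) || any(rho >= 1))
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  L * tracer$k1 * (1 - rho) + tracer$k2
}

#' Tracer occupancy with a rapidly dissociating competitor
#'
#' Limiting form of the competition kinetics when the competitor
#' equilibrates instantly with free receptor. Tracer binding is then
#' mono-exponential,
#' \deqn{[RL]_t = \frac{N[L]k_1(1-\rho_I)}{k_{obs,+I}}(1 - e^{-k_{obs,+I} t})}
#' with `rho_I = I/(Ki + I)` and `k_obs,+I = [L]k1(1-rho_I) + k2`. Only
#' the competitor's equilibrium affinity `Ki` enters; its rate constants
#' cancel.
#'
#' @param t Time (min), >= 0; vectorised.
#' @param tracer A [tracer_kinetics()] object.
#' @param rc A [rapid_competitor()] object.
#' @param L Tracer concentration (M), > 0.
#' @param I Competitor concentration (M), >= 0.
#' @return Specific-binding signal at each `t`; monotone nondecreasing.
#' @export
rapid_competition_occupancy <- function(t, tracer, rc, L, I) {
  stopifnot(is.numeric(t), all(t >= 0))
  check_positive(L = L)
  check_nonnegative(I = I)
  rho <- fractional_occupancy(I, rc$Ki)
  kobs <- observed_association_rate(L, tracer, rho)
  tracer$N * L * tracer$k1 * (1 - rho) / kobs * (1 - exp(-kobs * t))
}

#' Residence time and dissociation half-life
#'
#' The mean lifetime of the receptor-ligand complex is the reciprocal of
#' the dissociation rate constant, `RT = 1/koff`; the dissociation
#' half-life is `ln(2)/koff = RT * ln(2)`.
#'
#' @param koff Dissociation rate constant (min^-1), > 0; vectorised.
#' @return Time in minutes.
#' @examples
#' residence_time(0.0248)        # 40.32 min
#' dissociation_halflife(1) * 60 # 41.59 s
#' @export
residence_time <- function(koff) {
  check_positive(koff = koff)
  1 / koff
}

#' @rdname residence_time
#' @export
dissociation_halflife <- function(koff) {
  check_positive(koff = koff)
  log(2) / koff
}

#' A single well's binding time course
#'
#' @param times Sampling times (min), strictly increasing, >= 0.
#' @param signal Specific binding at each time point (signal units).
#' @param L Tracer concentration (M), > 0.
#' @param I Competitor concentration (M), >= 0.
#' @param well Optional well/replicate label.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, L, I = 0, well = "w1") {
  stopifnot(length(times) == length(signal), all(times >= 0))
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  check_positive(L = L)
  check_nonnegative(I = I)
  structure(list(times = times, signal = signal, L = L, I = I, well = well),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s': %d points over %.3g-%.3g min, L = %.3g M, I = %.3g M\n",
              x$well, length(x$times), min(x$times), max(x$times), x$L, x$I))
  invisible(x)
}

# ---- input guards ---------------------------------------------------------

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("`%s` must be positive and finite", nm), call. = FALSE)
  }
  invisible(TRUE)
}

check_nonnegative <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("`%s` must be nonnegative and finite", nm), call. = FALSE)
  }
  invisible(TRUE)
}
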