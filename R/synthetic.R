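#' Additive-noise model for simulated plates
#'
#' Plate reads on a BRET-ratio scale carry roughly constant read noise,
#' so the generators add independent Gaussian noise of fixed standard
#' deviation on the signal scale. A proportional component can be added
#' for heteroscedastic scenarios.
#'
#' @param sd_abs Additive Gaussian SD (signal units), >= 0.
#' @param sd_prop Optional proportional SD (fraction of the noiseless
#'   signal), >= 0.
#' @param seed Integer seed; identical seeds give identical plates.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_abs = 0, sd_prop = 0, seed = 1L) {
  check_nonnegative(sd_abs = sd_abs, sd_prop = sd_prop)
  structure(list(sd_abs = sd_abs, sd_prop = sd_prop,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Plate layout for simulated competition-kinetics experiments
#'
#' @param tracer_concs Tracer concentrations (M), > 0.
#' @param competitor_concs Competitor concentrations (M), >= 0; an
#'   `I = 0` control is expected for competition designs.
#' @param times Read times (min), strictly increasing from 0.
#' @param replicates Wells per condition.
#' @param nsb_conc Competitor concentration of the nonspecific-binding
#'   well (a saturating concentration of unlabelled antagonist).
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(tracer_concs, competitor_concs, times,
                         replicates = 1L, nsb_conc = 1e-5) {
  check_positive(tracer_concs = tracer_concs, nsb_conc = nsb_conc)
  check_nonnegative(competitor_concs = competitor_concs, times = times)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(tracer_concs = tracer_concs,
                 competitor_concs = competitor_concs,
                 times = times, replicates = as.integer(replicates),
                 nsb_conc = nsb_conc),
            class = "plate_design")
}

# Run code with a private RNG state derived from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

add_noise <- function(y, noise) {
  y + stats::rnorm(length(y), 0,
                   sqrt(noise$sd_abs^2 + (noise$sd_prop * abs(y))^2))
}

#' Simulate a competition-kinetics plate with known ground truth
#'
#' Generates tracer binding time courses for every combination of
#' tracer concentration, competitor concentration and replicate in the
#' design, using either the full competition model (when `truth` is a
#' [competitor_kinetics()]) or the rapid-dissociation model (when
#' `truth` is a [rapid_competitor()]), plus additive Gaussian noise.
#' One nonspecific-binding (NSB) well per tracer concentration and
#' replicate is included: a saturating competitor concentration leaves
#' no specific binding, so its trace is a flat zero-mean baseline.
#'
#' @param tracer A [tracer_kinetics()] object.
#' @param truth A [competitor_kinetics()] or [rapid_competitor()]
#'   object: the generating parameters, returned as the truth sidecar.
#' @param design A [plate_design()].
#' @param noise A [noise_model()].
#' @return A list with `data` (a long-format data frame in the trace
#'   CSV schema), `traces` (the non-NSB wells as [kinetic_trace()]
#'   objects) and `truth` (generating parameters, for recovery checks).
#' @export
gen_competition_plate <- function(tracer, truth, design,
                                  noise = noise_model()) {
  stopifnot(inherits(design, "plate_design"), inherits(noise, "noise_model"))
  is_rapid <- inherits(truth, "rapid_competitor")
  if (!is_rapid && !inherits(truth, "competitor_kinetics"))
    stop("`truth` must be competitor_kinetics or rapid_competitor",
         call. = FALSE)
  model_fn <- function(t, L, I) {
    if (is_rapid) rapid_competition_occupancy(t, tracer, truth, L, I)
    else motulsky_mahan_occupancy(t, tracer, truth, L, I)
  }
  with_seed(noise$seed, {
    rows <- list(); traces <- list(); w <- 0L
    for (rep_i in seq_len(design$replicates)) {
      for (L in design$tracer_concs) {
        for (I in design$competitor_concs) {
          w <- w + 1L
          well <- sprintf("w%03d", w)
          y <- add_noise(model_fn(design$times, L, I), noise)
          rows[[w]] <- data.frame(
            well = well, time_min = design$times, tracer_conc_M = L,
            competitor_conc_M = I, signal = y, is_nsb = 0L)
          traces[[length(traces) + 1L]] <-
            kinetic_trace(design$times, y, L = L, I = I, well = well)
        }
        # NSB well: saturating competitor, no specific binding
        w <- w + 1L
        rows[[w]] <- data.frame(
          well = sprintf("w%03d", w), time_min = design$times,
          tracer_conc_M = L, competitor_conc_M = design$nsb_conc,
          signal = add_noise(rep(0, length(design$times)), noise),
          is_nsb = 1L)
      }
    }
    truth_rec <- if (is_rapid)
      list(model = "rapid_dissociation", Ki = truth$Ki,
           pKi = -log10(truth$Ki),
           k1 = tracer$k1, k2 = tracer$k2, N = tracer$N)
    else
      list(model = "motulsky_mahan", k3 = truth$k3, k4 = truth$k4,
           Ki = truth$Ki, pKi = -log10(truth$Ki),
           k1 = tracer$k1, k2 = tracer$k2, N = tracer$N)
    list(data = do.call(rbind, rows), traces = traces, truth = truth_rec)
  })
}

#' Simulate a dose-response plate with known ground truth
#'
#' Raw signals follow a three-parameter logistic with unit Hill slope
#' plus additive Gaussian noise. Reference wells anchoring the 100% and
#' 0% normalisation are appended (`reference` column `ref_max` /
#' `ref_min`).
#'
#' @param pEC50 Generating midpoint (-log10 M).
#' @param top,bottom Generating plateaus (raw signal units).
#' @param concs Test concentrations (M), > 0.
#' @param noise A [noise_model()].
#' @param direction `"inhibition"` or `"stimulation"`.
#' @param n_ref Reference wells of each kind.
#' @return A list with `data` (dose-response CSV schema) and `truth`.
#' @export
gen_dose_response <- function(pEC50, top, bottom, concs,
                              noise = noise_model(),
                              direction = c("inhibition", "stimulation"),
                              n_ref = 2L) {
  direction <- match.arg(direction)
  check_positive(concs = concs)
  s_sign <- if (direction == "stimulation") 1 else -1
  mu <- bottom + (top - bottom) /
    (1 + 10^((-pEC50 - log10(concs)) * s_sign))
  with_seed(noise$seed, {
    y <- add_noise(mu, noise)
    ref_hi <- add_noise(rep(top, n_ref), noise)
    ref_lo <- add_noise(rep(bottom, n_ref), noise)
    data <- rbind(
      data.frame(well = sprintf("s%02d", seq_along(concs)), conc_M = concs,
                 raw_signal = y, reference = "none"),
      data.frame(well = sprintf("max%d", seq_len(n_ref)), conc_M = NA_real_,
                 raw_signal = ref_hi, reference = "ref_max"),
      data.frame(well = sprintf("min%d", seq_len(n_ref)), conc_M = NA_real_,
                 raw_signal = ref_lo, reference = "ref_min"))
    list(data = data,
         truth = list(pEC50 = pEC50, top = top, bottom = bottom,
                      direction = direction))
  })
}

#' Simulate a family of agonist curves under competitive antagonism
#'
#' Gaddum shift: at antagonist concentration `B`, the agonist EC50 is
#' multiplied by `1 + B/KB`, leaving plateaus untouched. Returns one
#' simulated dose-response dataset per antagonist concentration
#' (element `"0"` is the control curve), for downstream Schild
#' analysis.
#'
#' @param pEC50_control Agonist potency alone (-log10 M).
#' @param KB Antagonist equilibrium constant (M).
#' @param antagonist_concs Antagonist concentrations (M), > 0.
#' @param concs Agonist test concentrations (M).
#' @param top,bottom Plateaus.
#' @param noise A [noise_model()].
#' @param direction Curve direction.
#' @return Named list of [gen_dose_response()] outputs; names are the
#'   antagonist concentrations in molar.
#' @export
gen_schild_family <- function(pEC50_control, KB, antagonist_concs, concs,
                              top = 100, bottom = 0,
                              noise = noise_model(),
                              direction = "stimulation") {
  check_positive(KB = KB, antagonist_concs = antagonist_concs)
  B_all <- c(0, antagonist_concs)
  out <- lapply(seq_along(B_all), function(i) {
    shift <- 1 + B_all[i] / KB
    gen_dose_response(pEC50_control - log10(shift), top, bottom, concs,
                      noise = noise_model(noise$sd_abs, noise$sd_prop,
                                          noise$seed + i),
                      direction = direction)
  })
  names(out) <- as.character(B_all)
  out
}

#' Simulate a first-order depletion series
#'
#' Percent remaining decays as `100 exp(-k t)` with additive Gaussian
#' noise.
#'
#' @param k First-order depletion rate (min^-1), >= 0.
#' @param times Sampling times (min), strictly increasing.
#' @param noise A [noise_model()] (SD in percent units).
#' @param matrix Assay matrix label.
#' @param protein_conc Microsomal protein (mg/ul) or `NA`.
#' @return A list with `series` (a [depletion_series()]) and `truth`.
#' @export
gen_depletion <- function(k, times, noise = noise_model(),
                          matrix = "microsome", protein_conc = 1e-4) {
  check_nonnegative(k = k)
  with_seed(noise$seed, {
    pct <- add_noise(100 * exp(-k * times), noise)
    list(series = depletion_series(times, pct, matrix = matrix,
                                   protein_conc = protein_conc),
         truth = list(k = k, t_half = if (k > 0) log(2) / k else Inf))
  })
}

#' Reference simulation scenario: slow-off competitor
#'
#' The default kinetic fixture: tracer association/dissociation rates
#' typical of a fluorescent A3 receptor antagonist tracer used at 5 nM
#' (`k1 = 2.86e7` per molar per minute, `k2 = 0.4397` per minute), and
#' a slowly dissociating competitor (`k3 = 3.25e8`, `k4 = 0.0248`),
#' read over 0-60 minutes. With these rates the competitor leaves the
#' receptor more slowly than the tracer, producing the characteristic
#' transient overshoot of the tracer signal at intermediate competitor
#' concentrations.
#'
#' @return A list with `tracer`, `competitor`, `L` and default `times`.
#' @export
scenario_slow_competitor <- function() {
  list(tracer = tracer_kinetics(k1 = 2.86e7, k2 = 0.4397, N = 1),
       competitor = competitor_kinetics(k3 = 3.25e8, k4 = 0.0248),
       L = 5e-9,
       times = seq(0, 60, by = 2))
}
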