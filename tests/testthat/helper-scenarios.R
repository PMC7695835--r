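# Shared fixtures. The slow-competitor scenario (tracer k1 = 2.86e7
# M^-1 min^-1, k2 = 0.4397 min^-1 at L = 5 nM; competitor k3 = 3.25e8,
# k4 = 0.0248) is the package's reference kinetic condition.

slow_sc <- scenario_slow_competitor()

competition_design <- function(times = seq(0, 60, by = 2),
                               I = c(0, 1e-10, 1e-9, 1e-8, 1e-7)) {
  plate_design(slow_sc$L, I, times)
}

# Tracer-only association traces at several tracer concentrations.
tracer_traces <- function(Ls = c(5, 10, 20, 40) * 1e-9,
                          times = seq(0, 30, by = 2),
                          tracer = slow_sc$tracer, sd = 0, seed = 1L) {
  nm <- noise_model(sd_abs = sd, seed = seed)
  lapply(seq_along(Ls), function(i) {
    kobs <- Ls[i] * tracer$k1 + tracer$k2
    y <- tracer$N * Ls[i] * tracer$k1 / kobs * (1 - exp(-kobs * times))
    if (sd > 0) y <- with_seed(seed + i, y + rnorm(length(y), 0, sd))
    kinetic_trace(times, y, L = Ls[i], well = paste0("L", i))
  })
}

with_seed <- ligandkin:::with_seed

# Random log-uniform parameter draw for the mass-action system.
random_kinetic_pars <- function() {
  list(k1 = 10^runif(1, 5, 9), k2 = 10^runif(1, -2, 1),
       k3 = 10^runif(1, 5, 9), k4 = 10^runif(1, -2, 1),
       L = 10^runif(1, -10, -5), I = 10^runif(1, -10, -5))
}
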