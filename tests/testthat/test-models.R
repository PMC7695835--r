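test_that("competition occupancy starts at zero and reduces to mono-exponential at I = 0", {
  tr <- slow_sc$tracer
  cp <- slow_sc$competitor
  expect_equal(motulsky_mahan_occupancy(0, tr, cp, 5e-9, 1e-8), 0)
  expect_equal(rapid_competition_occupancy(0, tr, rapid_competitor(1e-8),
                                           5e-9, 1e-8), 0)

  # I = 0: both models collapse to N L k1/(L k1 + k2) (1 - e^{-(L k1 + k2) t})
  t <- seq(0, 20, by = 0.5)
  kobs <- 5e-9 * tr$k1 + tr$k2
  mono <- tr$N * 5e-9 * tr$k1 / kobs * (1 - exp(-kobs * t))
  expect_equal(motulsky_mahan_occupancy(t, tr, cp, 5e-9, 0), mono,
               tolerance = 1e-12)
  expect_equal(rapid_competition_occupancy(t, tr, rapid_competitor(1e-8),
                                           5e-9, 0), mono, tolerance = 1e-12)

  # t -> infinity plateau of the I = 0 curve: L k1 / (L k1 + k2) = 0.2454
  expect_equal(motulsky_mahan_occupancy(1e5, tr, cp, 5e-9, 0),
               0.143 / 0.5827, tolerance = 1e-4)
})

test_that("closed form matches numerical integration of the mass-action system", {
  # fixed reference parameters first
  t <- c(0.5, 1, 2, 5, 10, 20, 40, 60)
  for (I in c(1e-10, 1e-9, 1e-8)) {
    cf <- motulsky_mahan_occupancy(t, slow_sc$tracer, slow_sc$competitor,
                                   slow_sc$L, I)
    ode <- simulate_competition_ode(t, slow_sc$tracer, slow_sc$competitor,
                                    slow_sc$L, I)
    expect_lt(max(abs(cf - ode)) / max(ode), 1e-6)
  }
  # random parameter sets (log-uniform rates and concentrations)
  set.seed(42)
  for (i in 1:25) {
    p <- random_kinetic_pars()
    tr <- tracer_kinetics(p$k1, p$k2)
    cp <- competitor_kinetics(p$k3, p$k4)
    er <- eigen_rates(tr, cp, p$L, p$I)
    t <- seq(0, 5 / er$KS, length.out = 12)[-1]
    cf <- motulsky_mahan_occupancy(t, tr, cp, p$L, p$I)
    ode <- simulate_competition_ode(t, tr, cp, p$L, p$I)
    expect_lt(max(abs(cf - ode)) / max(abs(ode)), 1e-5)
  }
})

test_that("eigenrate algebraic identities hold to machine precision", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_kinetic_pars()
    tr <- tracer_kinetics(p$k1, p$k2)
    cp <- competitor_kinetics(p$k3, p$k4)
    er <- eigen_rates(tr, cp, p$L, p$I)
    expect_gte(er$KF, er$KS)
    expect_gt(er$KS, 0)
    expect_equal(er$KF + er$KS, er$KA + er$KB, tolerance = 1e-12)
    expect_equal(er$KF * er$KS,
                 p$k2 * p$k4 + p$k2 * p$k3 * p$I + p$k4 * p$k1 * p$L,
                 tolerance = 1e-9)
  }
})

test_that("repeated-root limit is continuous with the generic expression", {
  # KA == KB happens when I k3 + k4 == L k1 + k2; approach it from nearby
  tr <- tracer_kinetics(1e7, 0.1)
  L <- 1e-8
  KA <- L * tr$k1 + tr$k2          # 0.2
  t <- seq(0, 30, by = 0.5)
  # I = 0 and k4 == KA makes KF == KS exactly
  cp_eq <- competitor_kinetics(1e8, KA)
  y_eq <- motulsky_mahan_occupancy(t, tr, cp_eq, L, 0)
  cp_near <- competitor_kinetics(1e8, KA * (1 + 1e-7))
  y_near <- motulsky_mahan_occupancy(t, tr, cp_near, L, 0)
  expect_lt(max(abs(y_eq - y_near)) / max(y_eq), 1e-5)
  # and the limit form still matches the ODE oracle
  ode <- simulate_competition_ode(t[-1], tr, cp_eq, L, 0)
  expect_lt(max(abs(y_eq[-1] - ode)) / max(ode), 1e-6)
})

test_that("rapid model is the fast-dissociation limit of the full model", {
  Ki <- 1e-8
  t <- seq(0.1, 60, by = 0.1)
  dev <- sapply(c(1e2, 1e3, 1e4), function(k4) {
    cp <- competitor_kinetics(k4 / Ki, k4)
    a <- motulsky_mahan_occupancy(t, slow_sc$tracer, cp, slow_sc$L, Ki)
    b <- rapid_competition_occupancy(t, slow_sc$tracer,
                                     rapid_competitor(Ki), slow_sc$L, Ki)
    max(abs(a - b) / b)
  })
  expect_lt(dev[2], 0.01)              # within 1% at k4 = 1e3 min^-1
  expect_true(all(diff(dev) < 0))      # deviation shrinks as k4 grows
})

test_that("fractional occupancy and observed rate follow their closed forms", {
  expect_equal(fractional_occupancy(0, 1e-8), 0)
  expect_equal(fractional_occupancy(1e-8, 1e-8), 0.5)
  expect_equal(fractional_occupancy(9e-8, 1e-8), 0.9)
  expect_error(fractional_occupancy(1e-9, -1), "positive")

  tr <- slow_sc$tracer
  expect_equal(observed_association_rate(5e-9, tr, 0), 0.5827)
  expect_equal(observed_association_rate(5e-9, tr, 0.5), 0.5112)
  # rho -> 1: rate approaches k2 from above
  expect_equal(observed_association_rate(5e-9, tr, 1 - 1e-12), tr$k2,
               tolerance = 1e-9)
  expect_error(observed_association_rate(5e-9, tr, 1), "rho")
})

test_that("high competitor concentration abolishes rapid-model binding", {
  y <- rapid_competition_occupancy(seq(0, 60, 5), slow_sc$tracer,
                                   rapid_competitor(1e-9), slow_sc$L, 1e-2)
  expect_true(all(y < 1e-6))
})

test_that("residence time and dissociation half-life are reciprocal identities", {
  expect_equal(residence_time(0.0248), 40.32, tolerance = 1e-4)
  expect_equal(residence_time(1), 1)
  expect_equal(dissociation_halflife(1) * 60, 41.59, tolerance = 1e-4)
  expect_equal(dissociation_halflife(0.0248), residence_time(0.0248) * log(2))
  expect_error(residence_time(0), "positive")
  expect_error(dissociation_halflife(-1), "positive")
})

test_that("overshoot occurs exactly when the competitor out-stays the tracer", {
  tr <- slow_sc$tracer                 # k2 = 0.4397
  t <- seq(0, 400, by = 0.25)
  has_interior_max <- function(y) {
    i <- which.max(y)
    i > 1 && i < length(y) && y[i] > y[length(y)] * (1 + 1e-9)
  }
  for (ratio in c(0.056, 0.2, 0.5)) {  # k4 < k2: transient overshoot
    cp <- competitor_kinetics(3.25e8, tr$k2 * ratio)
    y <- motulsky_mahan_occupancy(t, tr, cp, slow_sc$L, 10 * cp$Ki)
    expect_true(has_interior_max(y), label = paste("overshoot at ratio", ratio))
    # the rapid model never overshoots, whatever the affinity
    yr <- rapid_competition_occupancy(t, tr, rapid_competitor(cp$Ki),
                                      slow_sc$L, 10 * cp$Ki)
    expect_false(has_interior_max(yr))
    expect_true(all(diff(yr) >= 0))
  }
  for (ratio in c(2, 5, 20)) {         # k4 > k2: monotone approach
    cp <- competitor_kinetics(3.25e8, tr$k2 * ratio)
    y <- motulsky_mahan_occupancy(t, tr, cp, slow_sc$L, 10 * cp$Ki)
    expect_false(has_interior_max(y), label = paste("no overshoot at ratio", ratio))
  }
})

test_that("domain errors are raised for invalid parameters", {
  expect_error(tracer_kinetics(-1, 0.4), "positive")
  expect_error(competitor_kinetics(1e8, 0), "positive")
  expect_error(rapid_competitor(-1e-9), "positive")
  expect_error(motulsky_mahan_occupancy(1, slow_sc$tracer,
                                        slow_sc$competitor, -5e-9, 0),
               "positive")
  expect_error(kinetic_trace(c(0, 2, 1), c(1, 2, 3), L = 1e-9),
               "increasing")
})

test_that("tracer KD is derived exactly as k2 / k1", {
  tr <- tracer_kinetics(2.86e7, 0.4397)
  expect_identical(tr$KD, 0.4397 / 2.86e7)
})
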