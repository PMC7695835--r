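test_that("tracer global fit recovers generating parameters from clean traces", {
  res <- fit_tracer_kinetics(tracer_traces())
  expect_lt(abs(res$tracer$k1 - slow_sc$tracer$k1) / slow_sc$tracer$k1, 1e-3)
  expect_lt(abs(res$tracer$k2 - slow_sc$tracer$k2) / slow_sc$tracer$k2, 1e-3)
  expect_equal(res$tracer$KD, res$tracer$k2 / res$tracer$k1)
  expect_true(res$fit$converged)
  expect_false(res$fit$ambiguous)
  # the linear kobs route is exact on exact kobs values
  expect_equal(res$kobs_regression$k2, slow_sc$tracer$k2, tolerance = 1e-6)
  expect_equal(res$kobs_regression$k1, slow_sc$tracer$k1, tolerance = 1e-6)
})

test_that("tracer fit rejects insufficient designs", {
  tr3 <- tracer_traces()
  expect_error(fit_tracer_kinetics(tr3[c(1, 1, 1)]), "insufficient design")
  short <- lapply(tr3, function(x)
    kinetic_trace(x$times[1:4], x$signal[1:4], x$L, x$I, x$well))
  expect_error(fit_tracer_kinetics(short), "insufficient design")
  with_I <- tr3
  with_I[[1]]$I <- 1e-9
  expect_error(fit_tracer_kinetics(with_I), "I = 0")
})

test_that("full competition fit recovers slow-competitor rate constants", {
  plate <- gen_competition_plate(slow_sc$tracer, slow_sc$competitor,
                                 competition_design(), noise_model(0))
  fit <- fit_competition_full(plate$traces, slow_sc$tracer)
  expect_lt(abs(fit$params[["k3"]] - plate$truth$k3) / plate$truth$k3, 1e-3)
  expect_lt(abs(fit$params[["k4"]] - plate$truth$k4) / plate$truth$k4, 1e-3)
  expect_equal(fit$Ki, fit$params[["k4"]] / fit$params[["k3"]])
  expect_equal(fit$RT, 1 / fit$params[["k4"]])
  expect_false(fit$ambiguous)
})

test_that("full fit on rapid-model data reports a fast or unresolved off-rate", {
  plate <- gen_competition_plate(
    slow_sc$tracer, rapid_competitor(1e-7),
    competition_design(I = c(0, 3e-8, 1e-7, 3e-7, 1e-6)),
    noise_model(0.01, seed = 11))
  fit <- fit_competition_full(plate$traces, slow_sc$tracer)
  expect_true(fit$ambiguous || fit$params[["k4"]] > 1)
})

test_that("rapid fit recovers affinity, including from fast-off full-model data", {
  pKi <- 6.92
  plate <- gen_competition_plate(
    slow_sc$tracer, rapid_competitor(10^-pKi),
    competition_design(I = 10^-pKi * c(0, 0.3, 1, 3, 10)),
    noise_model(0))
  fit <- fit_competition_rapid(plate$traces, slow_sc$tracer)
  expect_lt(abs(fit$pKi - pKi), 0.01)

  # data from the full model with k4 = 1e3 min^-1 are in the rapid regime
  Ki <- 1e-7
  plate2 <- gen_competition_plate(
    slow_sc$tracer, competitor_kinetics(1e3 / Ki, 1e3),
    competition_design(I = Ki * c(0, 0.3, 1, 3, 10)),
    noise_model(0))
  fit2 <- fit_competition_rapid(plate2$traces, slow_sc$tracer)
  expect_lt(abs(fit2$params[["Ki"]] - Ki) / Ki, 0.02)
})

test_that("competition fits reject degenerate designs", {
  plate <- gen_competition_plate(slow_sc$tracer, slow_sc$competitor,
                                 competition_design(), noise_model(0))
  one_I <- Filter(function(tr) tr$I %in% c(0, 1e-9), plate$traces)
  expect_error(fit_competition_full(one_I, slow_sc$tracer),
               "insufficient design")
  only_ctrl <- Filter(function(tr) tr$I == 0, plate$traces)
  expect_error(fit_competition_rapid(only_ctrl, slow_sc$tracer),
               "insufficient design")
  no_ctrl <- Filter(function(tr) tr$I > 0, plate$traces)
  expect_error(fit_competition_full(no_ctrl, slow_sc$tracer), "control")
})

test_that("partial F-test follows the extra-sum-of-squares formula", {
  mk <- function(ssr, dof, model = "m") {
    ligandkin:::new_fit_result(model, c(a = 1), c(a = 0.1), ssr, dof,
                               TRUE, dof + (20 - dof))
  }
  # equal SSR: F = 0, p = 1, simple wins
  cmp <- compare_models(mk(10, 18, "simple"), mk(10, 17, "complex"))
  expect_equal(cmp$f_stat, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$selected, "simple")
  # direct formula evaluation
  cmp2 <- compare_models(mk(20, 18, "simple"), mk(10, 17, "complex"))
  expect_equal(cmp2$f_stat, 17)
  expect_equal(cmp2$df_num, 1)
  expect_equal(cmp2$df_den, 17)
  expect_equal(cmp2$p_value, stats::pf(17, 1, 17, lower.tail = FALSE))
  expect_equal(cmp2$selected, "complex")
  # a better-fitting simple model clamps F at zero
  cmp3 <- compare_models(mk(9, 18, "simple"), mk(10, 17, "complex"))
  expect_equal(cmp3$f_stat, 0)
  expect_error(compare_models(mk(10, 17), mk(10, 18)), "degrees of freedom")
})

test_that("model selection matches dissociation speed on noisy plates", {
  # slow competitor (k4 << k2): the full model wins the F-test
  sel_slow <- vapply(1:5, function(s) {
    plate <- gen_competition_plate(slow_sc$tracer, slow_sc$competitor,
                                   competition_design(),
                                   noise_model(0.01, seed = s))
    fit_competition_auto(plate$traces, slow_sc$tracer,
                         n_starts = 3)$comparison$selected
  }, "")
  expect_gt(mean(sel_slow == "motulsky_mahan"), 0.5)
  # fast competitor (k4 >= 10 min^-1): the rapid model wins in the majority
  Ki <- 1e-7
  sel_fast <- vapply(1:7, function(s) {
    plate <- gen_competition_plate(
      slow_sc$tracer, competitor_kinetics(10 / Ki, 10),
      competition_design(I = Ki * c(0, 0.3, 1, 3, 10)),
      noise_model(0.01, seed = s))
    fit_competition_auto(plate$traces, slow_sc$tracer,
                         n_starts = 3)$comparison$selected
  }, "")
  expect_gt(mean(sel_fast == "rapid_dissociation"), 0.5)
})

test_that("noisy-fit estimates fall within three standard errors of truth", {
  n_ok <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    plate <- gen_competition_plate(slow_sc$tracer, slow_sc$competitor,
                                   competition_design(times = seq(0, 60, 4)),
                                   noise_model(0.02, seed = 100 + i))
    fit <- fit_competition_full(plate$traces, slow_sc$tracer, n_starts = 3)
    ok <- abs(fit$params[["k3"]] - 3.25e8) <= 3 * fit$se[["k3"]] &&
      abs(fit$params[["k4"]] - 0.0248) <= 3 * fit$se[["k4"]]
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n_rep, 0.9)
})

test_that("fits are invariant to trace order and consistent time rescaling", {
  plate <- gen_competition_plate(slow_sc$tracer, slow_sc$competitor,
                                 competition_design(),
                                 noise_model(0.01, seed = 9))
  f1 <- fit_competition_full(plate$traces, slow_sc$tracer)
  f2 <- fit_competition_full(rev(plate$traces), slow_sc$tracer)
  expect_equal(f1$params, f2$params, tolerance = 1e-6)

  # time in hours with rates in per-hour units: same Ki, k4 scaled by 60
  traces_h <- lapply(plate$traces, function(tr)
    kinetic_trace(tr$times / 60, tr$signal, tr$L, tr$I, tr$well))
  tracer_h <- tracer_kinetics(slow_sc$tracer$k1 * 60,
                              slow_sc$tracer$k2 * 60, slow_sc$tracer$N)
  f3 <- fit_competition_full(traces_h, tracer_h)
  expect_equal(f3$params[["k4"]], f1$params[["k4"]] * 60, tolerance = 1e-4)
  expect_equal(f3$Ki, f1$Ki, tolerance = 1e-4)
})
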