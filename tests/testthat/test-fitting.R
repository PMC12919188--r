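# Staged bounded identification: the convex inner gain problem, the
# acceleration-loop grid search, and the full staged procedure.

test_that("gains are recovered exactly when the target is generated by one loop", {
  com <- make_random_com(seed = 21)
  lam <- 0.050
  truth <- feedback_loop(k_a = 10, lambda_s = lam)
  tau <- loop_output(truth, com)
  loops <- list(feedback_loop(lambda_s = lam, com_sign = "both", torque_sign = "none"))
  fitted <- fit_gains_at_fixed_delays(com, tau, loops, fit_config())
  expect_equal(fitted[[1]]$k_a, 10, tolerance = 1e-6)
  expect_equal(fitted[[1]]$k_d, 0, tolerance = 1e-6)
  expect_equal(fitted[[1]]$k_v, 0, tolerance = 1e-6)
})

test_that("a target orthogonal to the regressors yields zero gains", {
  dt <- 0.001
  n <- 1251
  t0 <- -0.25
  # d/v/a all even about the window midpoint; target odd -> orthogonal
  tt <- t0 + (seq_len(n) - 1) * dt
  mid <- 0.5  # midpoint of the [0, 1] fit window
  ev <- cos(2 * pi * 1 * (tt - mid))
  od <- sin(2 * pi * 4 * (tt - mid))
  com <- com_state(time_series(ev, dt, t0), time_series(ev, dt, t0),
                   time_series(ev, dt, t0))
  tau <- time_series(od, dt, t0)
  loops <- list(feedback_loop(lambda_s = 0, com_sign = "both", torque_sign = "none"))
  fitted <- fit_gains_at_fixed_delays(com, tau, loops, fit_config())
  expect_equal(fitted[[1]]$k_d + fitted[[1]]$k_v + fitted[[1]]$k_a, 0,
               tolerance = 1e-6)
})

test_that("an active gain cap binds at the bound (dense grid oracle)", {
  com <- make_random_com(seed = 22)
  lam <- 0.060
  truth <- feedback_loop(k_a = 10, lambda_s = lam)
  tau <- loop_output(truth, com)
  # cap k_a at 5 via the scale multiplier: caps = mult * range(tau)/range(a);
  # with tau = 10*a(t-lam), range ratio is ~1/10 of k_a, so mult = 0.5 caps at ~5
  cfg <- fit_config(gain_scale_mult = 0.5)
  idx <- which(ts_time(tau) >= 0 & ts_time(tau) <= 1)
  cap <- 0.5 * diff(range(tau$values[idx])) / diff(range(com$a$values))
  loops <- list(feedback_loop(lambda_s = lam, com_sign = "both", torque_sign = "none"))
  fitted <- fit_gains_at_fixed_delays(com, tau, loops, cfg)
  expect_equal(fitted[[1]]$k_a, cap, tolerance = 1e-8)

  # dense brute-force grid confirms the constrained optimum sits at the cap
  a_col <- com$a$values[idx]
  y <- tau$values[idx]
  shift <- function(v, lag) c(rep(v[1], lag), v[seq_len(length(v) - lag)])
  a_lag <- shift(com$a$values, round(lam / 0.001))[idx]
  sse <- sapply(seq(0, cap, length.out = 200), function(k) sum((y - k * a_lag)^2))
  expect_equal(seq(0, cap, length.out = 200)[which.min(sse)], cap, tolerance = 1e-6)
})

test_that("rank-deficient regressors fall back to zero gains with a warning", {
  dt <- 0.001
  n <- 600
  z <- time_series(rep(0, n), dt, t0 = -0.25)
  s <- time_series(sin(2 * pi * 2 * (seq_len(n) - 1) * dt), dt, t0 = -0.25)
  com <- com_state(z, z, s)  # d and v identically zero -> degenerate columns
  tau <- time_series(rnorm(n), dt, t0 = -0.25)
  loops <- list(feedback_loop(lambda_s = 0.01, com_sign = "both", torque_sign = "none"))
  expect_warning(
    fitted <- fit_gains_at_fixed_delays(com, tau, loops,
                                        fit_config(fit_window = c(0, 0.3))),
    "rank-deficient")
  expect_equal(fitted[[1]]$k_d, 0)
  expect_equal(fitted[[1]]$k_v, 0)
})

test_that("the bounded least-squares core matches a dense brute-force search", {
  # 3-gain toy problem with sign constraints, solved by exhaustive grid
  set.seed(23)
  n <- 300
  X <- cbind(pmax(rnorm(n), 0), pmin(rnorm(n), 0), rnorm(n))
  g_true <- c(2, -1.5, 0.8)
  y <- drop(X %*% g_true) + rnorm(n, sd = 0.3)
  lo <- c(0, -3, -3); hi <- c(3, 0, 3)
  g_fit <- comfeedback:::bounded_lsq(X, y, lo, hi)
  grid <- seq(-3, 3, by = 0.05)
  best <- NULL
  for (g1 in grid[grid >= lo[1] & grid <= hi[1]])
    for (g2 in grid[grid >= lo[2] & grid <= hi[2]])
      for (g3 in grid) {
        sse <- sum((y - X %*% c(g1, g2, g3))^2)
        if (is.null(best) || sse < best$sse) best <- list(g = c(g1, g2, g3), sse = sse)
      }
  expect_equal(g_fit, best$g, tolerance = 0.05)  # within grid resolution
  expect_lte(sum((y - X %*% g_fit)^2), best$sse + 1e-8)
})

test_that("the acceleration loop is recovered by the delay grid search", {
  com <- make_random_com(seed = 24)
  truth <- feedback_loop(k_a = 8, lambda_s = 0.005)
  tau <- loop_output(truth, com)
  fit <- fit_acceleration_loop(com, tau, fit_config())
  expect_equal(fit$loop$k_a, 8, tolerance = 0.01)
  expect_lte(abs(fit$loop$lambda_s - 0.005), 0.005)
  expect_gt(fit$r2, 0.999)
})

test_that("noise uncorrelated with acceleration fits with near-zero R^2", {
  com <- make_random_com(seed = 25)
  set.seed(26)
  tau <- time_series(rnorm(length(com$a$values)), com$a$dt, com$a$t0)
  fit <- fit_acceleration_loop(com, tau, fit_config())
  expect_lt(fit$r2, 0.1)
})

test_that("a zero acceleration channel gives k_a = 0 and R^2 defined as 0", {
  dt <- 0.001
  n <- 1251
  z <- time_series(rep(0, n), dt, t0 = -0.25)
  d <- time_series(sin(2 * pi * (seq_len(n) - 1) * dt), dt, t0 = -0.25)
  com <- com_state(d, d, z)
  fit <- fit_acceleration_loop(com, d, fit_config())
  expect_equal(fit$loop$k_a, 0)
  expect_equal(fit$r2, 0)
})

test_that("fitting stops after stage 1 when the acceleration loop suffices", {
  study <- small_ramp_study()
  trw <- truncate_window(study$trials[[which(study$manifest$direction_deg == 90)[1]]],
                         0.25, 1.0)
  com <- com_state_from_trial(trw, "y")
  accel <- feedback_loop(k_a = 9, lambda_s = 0.008)
  base <- loop_output(accel, com)
  set.seed(27)
  noise <- rnorm(length(base$values), sd = 0.01 * diff(range(base$values)))
  tau <- time_series(base$values + noise, base$dt, base$t0, units = "Nm")
  fr <- fit_model(com, tau, fit_config(), mass_kg = 70)
  expect_true(fr$stopped_after_stage1)
  expect_identical(fr$active_parameters, 2L)
  expect_gt(fr$stage1_r2, 0.95)
  expect_true(all(vapply(fr$model$residual_loops,
                         function(l) l$k_d == 0 && l$k_v == 0 && l$k_a == 0,
                         logical(1))))
})

test_that("the stage-1 stopping rule honors the strict 95% threshold", {
  study <- small_ramp_study()
  trw <- truncate_window(study$trials[[which(study$manifest$direction_deg == 90)[1]]],
                         0.25, 1.0)
  com <- com_state_from_trial(trw, "y")
  accel <- feedback_loop(k_a = 9, lambda_s = 0.010)
  resid_loop <- feedback_loop(k_d = 300, k_v = 80, lambda_s = 0.100, com_sign = "-",
                              torque_sign = "-")
  base <- loop_output(accel, com)$values
  extra <- loop_output(resid_loop, com)$values

  # scale the residual component to put stage-1 R^2 on either side of 0.95
  stage1_r2_for <- function(c) {
    tau <- time_series(base + c * extra, com$d$dt, com$d$t0, units = "Nm")
    fit_acceleration_loop(com, tau, fit_config())$r2
  }
  cs <- seq(0, 5, by = 0.1)
  r2s <- vapply(cs, stage1_r2_for, numeric(1))
  c_above <- cs[max(which(r2s > 0.96))]
  c_below <- cs[min(which(r2s < 0.90))]

  fr_above <- fit_model(com, time_series(base + c_above * extra, com$d$dt, com$d$t0, "Nm"),
                        fit_config(), mass_kg = 70)
  expect_true(fr_above$stopped_after_stage1)
  expect_identical(fr_above$active_parameters, 2L)

  fr_below <- fit_model(com, time_series(base + c_below * extra, com$d$dt, com$d$t0, "Nm"),
                        fit_config(), mass_kg = 70)
  expect_false(fr_below$stopped_after_stage1)
  expect_true(any(vapply(fr_below$model$residual_loops,
                         function(l) l$k_d != 0 || l$k_v != 0 || l$k_a != 0,
                         logical(1))))
})

test_that("noiseless closed-loop data yields near-exact parameter recovery", {
  study <- small_ramp_study()
  trw <- truncate_window(study$trials[[which(study$manifest$direction_deg == 90)[1]]],
                         0.25, 1.0)
  com <- com_state_from_trial(trw, "y")
  gt <- study$plant$models$ramp$knee_flex
  tau <- remove_background_torque(trial_channel(trw, "tau_knee_flex_Nm"), 0, 0.25)$trace
  fr <- fit_model(com, tau, fit_config(), mass_kg = 70)
  expect_gt(fr$r2_train, 0.999)
  expect_false(fr$stopped_after_stage1)
  expect_equal(fr$model$accel_loop$k_a, gt$accel_loop$k_a, tolerance = 0.01)
  for (i in c(1, 4)) {
    tl <- gt$residual_loops[[i]]
    el <- fr$model$residual_loops[[i]]
    expect_equal(el$k_d, tl$k_d, tolerance = 0.01 * abs(tl$k_d))
    expect_equal(el$k_v, tl$k_v, tolerance = 0.01 * abs(tl$k_v))
    expect_lte(abs(el$lambda_s - tl$lambda_s), fit_config()$lambda_grid_step)
  }
  # total R^2 after stage 2 can only improve on stage 1
  expect_gte(fr$r2_train, fr$stage1_r2)
})

test_that("fitting is deterministic given the seed", {
  study <- small_ramp_study()
  trw <- truncate_window(study$trials[[which(study$manifest$direction_deg == 90)[1]]],
                         0.25, 1.0)
  com <- com_state_from_trial(trw, "y")
  tau <- remove_background_torque(trial_channel(trw, "tau_ankle_pf_Nm"), 0, 0.25)$trace
  f1 <- fit_model(com, tau, fit_config(seed = 99), mass_kg = 70)
  f2 <- fit_model(com, tau, fit_config(seed = 99), mass_kg = 70)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$r2_train, f2$r2_train)
})
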