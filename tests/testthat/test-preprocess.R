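# Averaging, exclusion, onset detection and sinusoid-residual extraction.

make_toy_trial <- function(values_by_channel, dt = 0.001, t0 = -0.25,
                           meta = list()) {
  channels <- lapply(values_by_channel, time_series, dt = dt, t0 = t0)
  base <- list(mass_kg = 70, onset_s = t0, condition_label = "ramp",
               direction_deg = 90, magnitude_label = "medium", rep_index = 1)
  base[names(meta)] <- meta
  ts_trial(channels, base)
}

test_that("averaging identical or cancelling trials behaves exactly", {
  x <- sin(seq(0, 2, by = 0.001))
  tr <- make_toy_trial(list(tau_ankle_pf_Nm = x))
  avg5 <- average_condition(replicate(5, tr, simplify = FALSE))
  expect_equal(avg5$trial$channels$tau_ankle_pf_Nm$values, x)
  expect_equal(avg5$n_trials, 5L)

  tr_neg <- make_toy_trial(list(tau_ankle_pf_Nm = -x), meta = list(rep_index = 2))
  avg0 <- average_condition(list(tr, tr_neg))
  expect_equal(avg0$trial$channels$tau_ankle_pf_Nm$values, rep(0, length(x)))
})

test_that("averaging n noisy replicates shrinks the residual by sqrt(n)", {
  set.seed(31)
  template <- sin(seq(0, 2, by = 0.001)) * 10
  sigma <- 0.8
  reps <- lapply(1:5, function(i) {
    make_toy_trial(list(tau_ankle_pf_Nm = template + rnorm(length(template), sd = sigma)),
                   meta = list(rep_index = i))
  })
  avg <- average_condition(reps)
  resid_sd <- sd(avg$trial$channels$tau_ankle_pf_Nm$values - template)
  expect_gt(resid_sd, sigma / sqrt(5) * 0.8)
  expect_lt(resid_sd, sigma / sqrt(5) * 1.2)
})

test_that("averaging refuses mixed condition keys and misaligned trials", {
  x <- rnorm(100)
  a <- make_toy_trial(list(tau_ankle_pf_Nm = x))
  b <- make_toy_trial(list(tau_ankle_pf_Nm = x), meta = list(direction_deg = 180))
  expect_error(average_condition(list(a, b)), "mixed condition keys")
  expect_error(average_condition(list()), "at least one")
})

test_that("the subtraction/average round trip returns the template exactly", {
  template <- cos(seq(0, 3, by = 0.001)) * 4
  offsets <- c(-1, 0.25, 0.75)  # residuals summing to zero
  reps <- lapply(seq_along(offsets), function(i) {
    make_toy_trial(list(tau_ankle_pf_Nm = template + offsets[i]),
                   meta = list(rep_index = i))
  })
  avg <- average_condition(reps)
  expect_equal(avg$trial$channels$tau_ankle_pf_Nm$values, template, tolerance = 1e-12)
})

test_that("the low-torque exclusion rule is a strict less-than at 10 Nm", {
  mk <- function(range_nm) {
    make_toy_trial(list(tau_ankle_pf_Nm = seq(0, range_nm, length.out = 100)))
  }
  expect_true(exclude_low_torque(mk(9.9), "ankle_pf"))
  expect_false(exclude_low_torque(mk(10.0), "ankle_pf"))
  expect_true(exclude_low_torque(make_toy_trial(list(tau_ankle_pf_Nm = rep(5, 100))),
                                 "ankle_pf"))
  expect_false(exclude_low_torque(mk(50), "ankle_pf", threshold_nm = 20))
  expect_true(exclude_low_torque(mk(15), "ankle_pf", threshold_nm = 20))
})

test_that("onset detection finds a sustained platform acceleration", {
  dt <- 0.001
  acc <- c(rep(0, 400), rep(0.5, 200), rep(0, 100))
  tr <- make_toy_trial(list(plat_acc_x_mps2 = acc,
                            plat_acc_y_mps2 = rep(0, length(acc))),
                       t0 = 0, meta = list(onset_s = 0.4))
  expect_equal(detect_onset(tr), 0.4, tolerance = 1e-9)
  quiet <- make_toy_trial(list(plat_acc_x_mps2 = rep(0, 500),
                               plat_acc_y_mps2 = rep(0, 500)),
                          t0 = 0, meta = list(onset_s = 0.1))
  expect_error(detect_onset(quiet), "no sustained")
})

test_that("superimposed-perturbation extraction recovers an injected response", {
  plant <- plant_params(noise_frac = 0)
  study <- generate_study(plant, seed = 41, directions_deg = numeric(0),
                          magnitudes = character(0), ramp_reps = 1,
                          sinusoid_reps = 2, sinusoid_contexts = c("none", "slow"))
  m <- study$manifest
  base <- study$trials[m$trial_id[m$condition_label == "sinusoid" & m$plane == "sagittal" &
                                    m$start_sign == 1]]
  pert <- study$trials[m$trial_id[m$condition_label == "sinusoid_perturbed" &
                                    m$plane == "sagittal" & m$start_sign == 1]]
  base_avg <- average_condition(base)

  # a perturbation-free sinusoid minus its own average is zero everywhere
  self_res <- base[[1]]$channels$tau_ankle_pf_Nm$values -
    base_avg$trial$channels$tau_ankle_pf_Nm$values
  expect_lt(max(abs(self_res)), 1e-9)

  segs <- extract_superimposed_response(pert[[1]], base_avg)
  expect_length(segs, nrow(pert[[1]]$meta$superimposed))
  for (s in segs) {
    expect_equal(length(s$channels[[1]]$values), 1251)
    expect_equal(s$meta$onset_s, 0)
    expect_equal(s$channels[[1]]$t0, -0.25)
  }

  # injection recovery: the residual CoM of each segment, pushed through the
  # sinusoid-context ground truth, reproduces the residual torque. The model
  # is quasi-linear (rectified), so subtraction is exact only where the
  # rectification gates match between perturbed and unperturbed trials; the
  # match must hold to a few percent of the response scale.
  gt <- plant$models$sinusoid$knee_flex
  s1 <- segs[[1]]
  com <- com_state_from_trial(s1, "y")
  pred <- predict_torque(gt, com)
  tau <- trial_channel(s1, "tau_knee_flex_Nm")
  rel <- max(abs(tau$values - pred$values)) / diff(range(tau$values))
  expect_lt(rel, 0.15)
  expect_gt(compute_r2(tau, pred), 0.95)
})

test_that("accelerating and braking classes follow the platform motion", {
  plant <- plant_params(noise_frac = 0)
  study <- generate_study(plant, seed = 42, directions_deg = numeric(0),
                          magnitudes = character(0), ramp_reps = 1,
                          sinusoid_reps = 2, sinusoid_contexts = c("none", "slow"))
  m <- study$manifest
  base_avg <- average_condition(
    study$trials[m$trial_id[m$condition_label == "sinusoid" & m$plane == "sagittal" &
                              m$start_sign == 1]])
  pert <- study$trials[m$trial_id[m$condition_label == "sinusoid_perturbed" &
                                    m$plane == "sagittal" & m$start_sign == 1]][[1]]
  segs <- extract_superimposed_response(pert, base_avg)
  expected <- pert$meta$superimposed$class
  got <- vapply(segs, function(s) s$meta$class, character(1))
  expect_equal(got, expected)
})

test_that("a phase-shifted trial is rejected", {
  plant <- plant_params(noise_frac = 0)
  study <- generate_study(plant, seed = 43, directions_deg = numeric(0),
                          magnitudes = character(0), ramp_reps = 1,
                          sinusoid_reps = 2, sinusoid_contexts = c("none", "slow"))
  m <- study$manifest
  base_avg <- average_condition(
    study$trials[m$trial_id[m$condition_label == "sinusoid" & m$plane == "sagittal" &
                              m$start_sign == 1]])
  pert <- study$trials[m$trial_id[m$condition_label == "sinusoid_perturbed" &
                                    m$plane == "sagittal" & m$start_sign == 1]][[1]]
  shift_n <- 30
  pert$channels <- lapply(pert$channels, function(ch) delay_signal(ch, shift_n * ch$dt))
  expect_error(extract_superimposed_response(pert, base_avg), "phase mismatch")
})
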