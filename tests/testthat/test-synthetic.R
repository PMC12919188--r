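# Platform profiles, closed-loop simulation and the study protocol.

test_that("ramp profiles reach the specified displacement and peak velocity", {
  specs <- ramp_specs()
  prof <- make_ramp_profile(specs$large)
  expect_equal(max(prof$pos$values), 0.126, tolerance = 1e-9)
  expect_equal(prof$pos$values[length(prof$pos$values)], 0.126, tolerance = 1e-9)
  expect_equal(max(abs(prof$vel$values)), 0.24, tolerance = 1e-9)
  expect_equal(max(prof$acc$values), 1.6 * 9.81, tolerance = 1e-9)

  zero <- make_ramp_profile(perturbation_spec(0, 0.1, 1))
  expect_true(all(zero$pos$values == 0))
  expect_true(all(zero$acc$values == 0))

  expect_error(perturbation_spec(0.001, 0.24, 1.6), "infeasible")
})

test_that("small-slow cruise duration matches trapezoid kinematics", {
  s <- ramp_specs()$small_slow
  a <- 1.06 * 9.81
  t_cruise <- (0.049 - 0.16^2 / a) / 0.16
  prof <- make_ramp_profile(s)
  measured <- sum(abs(prof$vel$values - 0.16) < 1e-9) * prof$vel$dt
  expect_equal(measured, t_cruise, tolerance = 0.002)
})

test_that("profile velocity and acceleration are consistent derivatives", {
  for (prof in list(make_ramp_profile(ramp_specs()$medium),
                    make_sinusoid_profile(sinusoid_spec()))) {
    dt <- prof$pos$dt
    num_vel <- diff(prof$pos$values) / dt
    mid_vel <- (prof$vel$values[-1] + prof$vel$values[-length(prof$vel$values)]) / 2
    expect_lt(max(abs(num_vel - mid_vel)), 25 * dt)  # O(dt) with |jerk| bounded
    num_acc <- diff(prof$vel$values) / dt
    mid_acc <- (prof$acc$values[-1] + prof$acc$values[-length(prof$acc$values)]) / 2
    expect_lt(max(abs(num_acc - mid_acc)), 16000 * dt)
  }
})

test_that("sinusoid profile peaks at 7.7 cm with zero crossings every half period", {
  prof <- make_sinusoid_profile(sinusoid_spec())
  expect_equal(max(abs(prof$pos$values)), 0.077, tolerance = 1e-6)
  f <- 0.75
  for (k in 3:17) {
    tk <- k / (2 * f)
    i <- round(tk / prof$pos$dt) + 1
    # crossings need not fall on the sample grid; bound by one sample's slope
    expect_lt(abs(prof$pos$values[i]), 0.077 * 2 * pi * f * prof$pos$dt)
  }
  # taper: the on-ramp suppresses the first half cycle's peak
  first_peak <- max(abs(prof$pos$values[seq_len(round(1 / (2 * f) / prof$pos$dt))]))
  expect_lt(first_peak, 0.077 * 0.8)
})

test_that("superimposed ramps are signed by their accelerating/braking class", {
  sup <- data.frame(crossing = c(5, 9), label = "small_slow",
                    class = c("accelerating", "braking"))
  prof <- make_sinusoid_profile(sinusoid_spec(start_sign = 1, superimposed = sup))
  f <- 0.75
  # at crossing k the platform velocity sign is start_sign * (-1)^k
  expect_equal(prof$injections$sign, c(-1, -(-1)))
  expect_equal(prof$injections$onset_s, c(5, 9) / (2 * f))

  overlap <- data.frame(crossing = c(5, 5), label = "small_slow",
                        class = c("accelerating", "braking"))
  expect_error(make_sinusoid_profile(sinusoid_spec(superimposed = overlap)),
               "overlapping")
})

test_that("zero platform motion leaves every channel at baseline", {
  plant <- plant_params(noise_frac = 0.02)
  n <- 1000
  platform <- list(acc_x = rep(0, n), acc_y = rep(0, n))
  tr <- simulate_trial(platform, plant, meta = list(onset_s = 0.2), seed = 5)
  for (ch in names(tr$channels)) {
    expect_true(all(tr$channels[[ch]]$values == 0), info = ch)
  }
})

test_that("noiseless torque channels equal the ground-truth model prediction", {
  plant <- plant_params(noise_frac = 0)
  prof <- make_ramp_profile(ramp_specs()$medium)
  platform <- comfeedback:::embed_ramp(prof, 90, 0.5, 2.0, 0.001)
  tr <- simulate_trial(platform, plant, meta = list(onset_s = 0.5), seed = NULL)
  com <- com_state_from_trial(tr, "y")
  for (j in c("ankle_pf", "knee_flex", "hip_flex")) {
    pred <- predict_torque(plant$models$ramp[[j]], com)
    rec <- trial_channel(tr, sprintf("tau_%s_Nm", j))
    expect_lt(max(abs(rec$values - pred$values)), 1e-9)
  }
})

test_that("simulation is deterministic given the seed", {
  plant <- plant_params()
  prof <- make_ramp_profile(ramp_specs()$small_fast)
  platform <- comfeedback:::embed_ramp(prof, 0, 0.5, 2.0, 0.001)
  t1 <- simulate_trial(platform, plant, meta = list(onset_s = 0.5), seed = 77)
  t2 <- simulate_trial(platform, plant, meta = list(onset_s = 0.5), seed = 77)
  expect_identical(t1$channels$com_d_x_m$values, t2$channels$com_d_x_m$values)
  t3 <- simulate_trial(platform, plant, meta = list(onset_s = 0.5), seed = 78)
  expect_false(identical(t1$channels$com_d_x_m$values, t3$channels$com_d_x_m$values))
})

test_that("an unstable plant reports divergence", {
  models <- default_plant_models(70)
  # destabilize the frontal plane: displacement gain far below the gravity line
  models$ramp$hip_add$residual_loops[[1]]$k_d <- 10
  models$ramp$hip_add$residual_loops[[4]]$k_d <- 10
  models$ramp$hip_add$residual_loops[[1]]$k_v <- 0
  models$ramp$hip_add$residual_loops[[4]]$k_v <- 0
  plant <- plant_params(noise_frac = 0, models = models)
  prof <- make_ramp_profile(ramp_specs()$large, hold_s = 3)
  platform <- comfeedback:::embed_ramp(prof, 0, 0.5, 5.0, 0.001)
  expect_error(simulate_trial(platform, plant, meta = list(onset_s = 0.5)),
               "divergence")
})

test_that("the full protocol enumerates 160 ramp and 36 sinusoid-block trials", {
  man <- study_manifest()
  expect_identical(sum(man$condition_label == "ramp"), 160L)
  expect_identical(sum(man$condition_label %in% c("sinusoid", "sinusoid_perturbed")), 36L)
  expect_identical(nrow(man), 196L)
  # 8 directions x 4 magnitudes x 5 reps; 2 planes x 3 contexts x 6 reps
  ramps <- man[man$condition_label == "ramp", ]
  expect_identical(length(unique(ramps$direction_deg)), 8L)
  expect_identical(length(unique(ramps$magnitude_label)), 4L)
  sins <- man[man$condition_label != "ramp", ]
  expect_identical(as.integer(table(sins$plane)), c(18L, 18L))
  # each sinusoid condition starts 3 times in either direction
  by_cond <- split(sins$start_sign, paste(sins$plane, sins$condition_label,
                                          sins$magnitude_label))
  for (ss in by_cond) expect_equal(sum(ss > 0), 3L)
})

test_that("superimposed onsets sit at zero crossings of the background sinusoid", {
  plant <- plant_params(noise_frac = 0)
  study <- generate_study(plant, seed = 51, directions_deg = numeric(0),
                          magnitudes = character(0), ramp_reps = 1,
                          sinusoid_reps = 1, sinusoid_contexts = "fast")
  m <- study$manifest
  id <- m$trial_id[m$condition_label == "sinusoid_perturbed"][1]
  tr <- study$trials[[id]]
  f <- tr$meta$frequency_hz
  onset <- tr$meta$onset_s
  for (t_sup in tr$meta$superimposed$onset_s) {
    phase <- (t_sup - onset) * 2 * f
    expect_equal(phase, round(phase), tolerance = 1e-9)
  }
})

test_that("study generation is reproducible and carries ground truth", {
  s1 <- generate_study(plant_params(), seed = 52, directions_deg = 90,
                       magnitudes = "medium", ramp_reps = 2,
                       sinusoid_contexts = character(0))
  s2 <- generate_study(plant_params(), seed = 52, directions_deg = 90,
                       magnitudes = "medium", ramp_reps = 2,
                       sinusoid_contexts = character(0))
  expect_identical(s1$trials[[1]]$channels$com_d_y_m$values,
                   s2$trials[[1]]$channels$com_d_y_m$values)
  expect_s3_class(s1$plant$models$ramp$ankle_pf, "com_feedback_model")

  dir <- file.path(tempdir(), "study_rt")
  write_study(s1, dir)
  back <- read_study(dir)
  expect_equal(back$manifest$trial_id, s1$manifest$trial_id)
  expect_equal(back$trials[[1]]$channels$com_d_y_m$values,
               s1$trials[[1]]$channels$com_d_y_m$values, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  unlink(dir, recursive = TRUE)
})
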