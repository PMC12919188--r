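# Signal primitives: zero-phase filtering, resampling, delays, rectification,
# windowing.

test_that("lowpass filter passes DC and the deep passband, rejects far stopband", {
  dt <- 0.001
  x_const <- time_series(rep(2.5, 2000), dt)
  expect_equal(lowpass_filter(x_const, 10, 4)$values, rep(2.5, 2000),
               tolerance = 1e-5)

  t <- (0:9999) * dt
  amp_ratio <- function(f_sig, cutoff) {
    x <- time_series(sin(2 * pi * f_sig * t), dt)
    y <- lowpass_filter(x, cutoff, 4)
    core <- 2000:8000  # away from edge transients
    max(abs(y$values[core])) / max(abs(x$values[core]))
  }
  expect_gt(amp_ratio(0.1, 10), 0.99)    # cutoff/100: attenuation < 1%
  expect_lt(amp_ratio(100, 10), 0.01)    # 10x cutoff: attenuation > 99%
})

test_that("measured stopband attenuation matches the squared analytic filter response", {
  # zero-phase = forward + backward pass, so the amplitude response is the
  # magnitude response of the designed (half-order) filter, squared
  dt <- 0.001
  cutoff <- 10
  f_sig <- 100
  bf <- signal::butter(2, cutoff / (0.5 / dt), type = "low")
  z <- exp(-1i * 2 * pi * f_sig * dt)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  expected <- Mod(H)^2
  t <- (0:19999) * dt
  x <- time_series(sin(2 * pi * f_sig * t), dt)
  y <- lowpass_filter(x, cutoff, 4)
  core <- 5000:15000
  measured <- max(abs(y$values[core]))
  expect_equal(measured, expected, tolerance = 0.1)
})

test_that("lowpass filter is idempotent in the deep passband", {
  dt <- 0.001
  t <- (0:9999) * dt
  x <- time_series(sin(2 * pi * 0.1 * t), dt)
  once <- lowpass_filter(x, 10, 4)
  twice <- lowpass_filter(once, 10, 4)
  core <- 2000:8000
  ratio <- max(abs(twice$values[core])) / max(abs(once$values[core]))
  expect_gt(ratio, 0.99)
  expect_lt(ratio, 1.01)
})

test_that("lowpass filter validates its arguments", {
  x <- time_series(rnorm(100), 0.001)
  expect_error(lowpass_filter(x, 500, 4), "cutoff")
  expect_error(lowpass_filter(x, 600, 4), "cutoff")
  expect_error(lowpass_filter(x, 10, 3), "even")
  expect_error(lowpass_filter(time_series(1, 0.001), 10, 4), "2 samples")
})

test_that("linear resampling is exact on affine signals and preserves endpoints", {
  x <- time_series(seq(0, 5, length.out = 101), dt = 0.01, t0 = 1)
  y <- resample_linear(x, 1000)
  expect_equal(y$dt, 0.001)
  expect_equal(y$t0, 1)
  expect_equal(y$values, seq(0, 5, length.out = 1001), tolerance = 1e-12)
  expect_equal(y$values[1], x$values[1])
  expect_equal(y$values[length(y$values)], x$values[length(x$values)])

  # resampling to the original rate is the identity
  z <- resample_linear(x, 100)
  expect_equal(z$values, x$values, tolerance = 1e-12)
})

test_that("upsampling error of a sine respects the interpolation bound", {
  f <- 3
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  x <- time_series(sin(2 * pi * f * t), dt)
  y <- resample_linear(x, 1000)
  truth <- sin(2 * pi * f * ts_time(y))
  bound <- (2 * pi * f * dt)^2 / 8
  expect_lt(max(abs(y$values - truth)), bound)
})

test_that("delay_signal shifts by whole samples and back-fills the lead", {
  dt <- 0.001
  x <- time_series(c(rep(0, 100), rep(1, 100)), dt)  # step at t = 0.100 s
  expect_identical(delay_signal(x, 0), x)

  y <- delay_signal(x, 0.05)
  expect_equal(which(y$values == 1)[1], 151)  # step moved to t = 0.150 s
  expect_equal(length(y$values), length(x$values))

  # fractional delays round to the nearest sample: 52.3 ms -> 52 samples
  z <- time_series(seq_len(200), dt)
  y2 <- delay_signal(z, 0.0523)
  expect_equal(y2$values, c(rep(1, 52), seq_len(148)))

  # the leading gap takes the first value (quiescent background)
  x2 <- time_series(c(5, 1:9), dt)
  expect_equal(delay_signal(x2, 0.003)$values[1:3], rep(5, 3))

  expect_error(delay_signal(x, 1), "longer than the record")
  expect_error(delay_signal(x, -0.1), ">= 0")
})

test_that("composed delays equal the summed delay on the record interior", {
  set.seed(5)
  x <- time_series(cumsum(rnorm(500)), 0.001)
  ab <- delay_signal(delay_signal(x, 0.012), 0.023)
  once <- delay_signal(x, 0.035)
  interior <- 40:500
  expect_equal(ab$values[interior], once$values[interior])
})

test_that("halfwave_split partitions any signal exactly", {
  x <- time_series(c(-1, 2, 0), 0.01)
  hw <- halfwave_split(x)
  expect_equal(hw$pos$values, c(0, 2, 0))
  expect_equal(hw$neg$values, c(-1, 0, 0))

  y <- time_series(c(0, 1, 3), 0.01)
  hwy <- halfwave_split(y)
  expect_equal(hwy$pos$values, y$values)
  expect_equal(hwy$neg$values, rep(0, 3))

  set.seed(7)
  for (i in 1:20) {
    z <- time_series(rnorm(50), 0.01)
    hz <- halfwave_split(z)
    expect_equal(hz$pos$values + hz$neg$values, z$values)
    expect_true(all(hz$pos$values >= 0) && all(hz$neg$values <= 0))
  }
})

test_that("truncate_window uses inclusive endpoints and re-bases the onset", {
  dt <- 0.001
  n <- 3001
  ch <- list(a = time_series(seq_len(n), dt, t0 = 0))
  tr <- ts_trial(ch, meta = list(mass_kg = 70, onset_s = 1.0))

  w <- truncate_window(tr, 0.25, 1.0)
  expect_equal(length(w$channels$a$values), 1251)
  expect_equal(w$meta$onset_s, 0)
  expect_equal(w$channels$a$t0, -0.25)
  # the sample at the onset is preserved
  expect_equal(w$channels$a$values[251], 1001)

  single <- truncate_window(tr, 0, 0)
  expect_equal(length(single$channels$a$values), 1)
  expect_equal(single$channels$a$values, 1001)

  expect_error(truncate_window(tr, 1.5, 1.0), "exceeds")
})

test_that("the sinusoid analysis window spans -0.25 to +15 s", {
  dt <- 0.001
  n <- 16001
  ch <- list(a = time_series(rep(0, n), dt, t0 = 0))
  tr <- ts_trial(ch, meta = list(mass_kg = 70, onset_s = 0.5))
  w <- truncate_window(tr, 0.25, 15.0)
  expect_equal(length(w$channels$a$values), 15251)
  expect_equal(ts_time(w$channels$a)[1], -0.25)
  expect_equal(ts_end(w$channels$a), 15.0)
})

test_that("trial CSV + JSON sidecar round-trips", {
  dt <- 0.001
  ch <- list(com_d_y_m = time_series(sin(1:100), dt, units = "m"),
             tau_ankle_pf_Nm = time_series(cos(1:100), dt, units = "Nm"))
  meta <- list(participant_id = "S01", mass_kg = 68.5, condition_label = "ramp",
               direction_deg = 90, magnitude_label = "large", onset_s = 0.05,
               rep_index = 2)
  tr <- ts_trial(ch, meta)
  path <- file.path(tempdir(), "trial_rt.csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(back$channels$com_d_y_m$values, tr$channels$com_d_y_m$values)
  expect_equal(back$channels$tau_ankle_pf_Nm$units, "Nm")
  expect_equal(back$meta$mass_kg, 68.5)
  expect_equal(back$meta$direction_deg, 90)
  unlink(c(path, sub("csv$", "json", path)))
})
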