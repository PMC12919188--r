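# Shared fixtures, generated in code.

# a smooth random com_state (sum of low-frequency sinusoids), 1 kHz
make_random_com <- function(seed = 1, n = 1251, t0 = -0.25, axis = "y") {
  set.seed(seed)
  dt <- 0.001
  t <- t0 + (seq_len(n) - 1) * dt
  f <- runif(3, 0.5, 4)
  amp <- rnorm(3, sd = 0.01)
  ph <- runif(3, 0, 2 * pi)
  w <- 2 * pi * f
  d <- rowSums(sapply(1:3, function(i) amp[i] * sin(w[i] * t + ph[i])))
  v <- rowSums(sapply(1:3, function(i) amp[i] * w[i] * cos(w[i] * t + ph[i])))
  a <- rowSums(sapply(1:3, function(i) -amp[i] * w[i]^2 * sin(w[i] * t + ph[i])))
  com_state(time_series(d, dt, t0, "m"),
            time_series(v, dt, t0, "m/s"),
            time_series(a, dt, t0, "m/s^2"), axis = axis)
}

# a model with the canonical residual gating and given active loops
make_test_model <- function(joint = "ankle_pf", axis = "y",
                            ka = 0, lam_a = 0.010,
                            loops = list()) {
  gat <- list(c("+", "+"), c("+", "-"), c("-", "+"), c("-", "-"))
  res <- lapply(gat, function(g) {
    feedback_loop(com_sign = g[1], torque_sign = g[2], lambda_s = 0.1)
  })
  for (l in loops) {
    i <- which(vapply(gat, function(g) g[1] == l$com_sign && g[2] == l$torque_sign,
                      logical(1)))
    res[[i]] <- feedback_loop(l$k_d %||% 0, l$k_v %||% 0, l$k_a %||% 0,
                              l$lambda_s, com_sign = l$com_sign,
                              torque_sign = l$torque_sign)
  }
  com_feedback_model(joint, axis,
                     accel_loop = feedback_loop(k_a = ka, lambda_s = lam_a),
                     residual_loops = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal small ramp study shared by several tests (cached per session)
small_ramp_study <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_frac = 0, seed = 11, directions = c(0, 90),
           magnitudes = "medium", reps = 1) {
    key <- paste(noise_frac, seed, paste(directions, collapse = "-"),
                 paste(magnitudes, collapse = "-"), reps, sep = "|")
    if (is.null(cache[[key]])) {
      plant <- plant_params(noise_frac = noise_frac)
      cache[[key]] <- generate_study(plant, seed = seed,
                                     directions_deg = directions,
                                     magnitudes = magnitudes,
                                     ramp_reps = reps,
                                     sinusoid_contexts = character(0))
    }
    cache[[key]]
  }
})
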