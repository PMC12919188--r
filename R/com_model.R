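# The delayed CoM feedback torque model: one instantaneous acceleration loop
# plus four sign-gated residual loops, each mapping half-wave-rectified,
# time-delayed CoM kinematics into joint torque through displacement,
# velocity and acceleration gains sharing a single loop delay.

#' CoM kinematic state along one horizontal axis
#'
#' Displacement, velocity and acceleration of the body centre of mass
#' relative to the feet, on a shared time base, for one horizontal axis
#' (`"x"` = frontal plane, `"y"` = sagittal plane).
#'
#' @param d,v,a `time_series` of CoM displacement (m), velocity (m/s) and
#'   acceleration (m/s^2) relative to the feet.
#' @param axis Axis label, `"x"`, `"y"` or `NA`.
#'
#' @return An object of class `"com_state"`.
#' @export
com_state <- function(d, v, a, axis = NA_character_) {
  for (ch in list(d, v, a)) stopifnot(inherits(ch, "time_series"))
  same <- isTRUE(all.equal(d$t0, v$t0)) && isTRUE(all.equal(d$t0, a$t0)) &&
    isTRUE(all.equal(d$dt, v$dt)) && isTRUE(all.equal(d$dt, a$dt)) &&
    length(d$values) == length(v$values) && length(d$values) == length(a$values)
  if (!same) stop("d, v, a must share t0, dt and length", call. = FALSE)
  if (!is.na(axis) && !axis %in% c("x", "y")) stop("`axis` must be 'x', 'y' or NA", call. = FALSE)
  structure(list(d = d, v = v, a = a, axis = axis), class = "com_state")
}

#' @export
print.com_state <- function(x, ...) {
  cat(sprintf("<com_state> axis %s, %d samples @ %.6g Hz\n",
              x$axis, length(x$d$values), 1 / x$d$dt))
  invisible(x)
}

#' Build a CoM state from the channels of a trial
#'
#' @param trial A `ts_trial` carrying channels `com_d_<axis>_m`,
#'   `com_v_<axis>_mps` and `com_a_<axis>_mps2`.
#' @param axis `"x"` (frontal) or `"y"` (sagittal).
#' @return A `com_state`.
#' @export
com_state_from_trial <- function(trial, axis) {
  axis <- match.arg(axis, c("x", "y"))
  com_state(
    d = trial_channel(trial, sprintf("com_d_%s_m", axis)),
    v = trial_channel(trial, sprintf("com_v_%s_mps", axis)),
    a = trial_channel(trial, sprintf("com_a_%s_mps2", axis)),
    axis = axis
  )
}

#' Create one delayed feedback loop
#'
#' A loop maps the CoM state into torque as
#' `tau(t) = k_d * s_d(t - lambda) + k_v * s_v(t - lambda) + k_a * s_a(t - lambda)`,
#' where `s_•` is the half-wave component of each CoM channel selected by
#' `com_sign` (the full signal when `com_sign = "both"`), and all three terms
#' share one delay. `torque_sign` records which signed part of the torque
#' response the loop is intended to reconstruct; during fitting it is
#' enforced through sign bounds on the gains (not by clipping the output,
#' which would break linearity in the gains).
#'
#' @param k_d Displacement gain (Nm/m).
#' @param k_v Velocity gain (Nm s/m).
#' @param k_a Acceleration gain (Nm s^2/m).
#' @param lambda_s Common loop delay in seconds (>= 0).
#' @param com_sign Which half-wave of the CoM input the loop sees:
#'   `"+"`, `"-"` or `"both"`.
#' @param torque_sign Which signed torque component the loop reconstructs:
#'   `"+"`, `"-"` or `"none"` (unconstrained).
#'
#' @return An object of class `"feedback_loop"`.
#' @export
feedback_loop <- function(k_d = 0, k_v = 0, k_a = 0, lambda_s = 0,
                          com_sign = c("both", "+", "-"),
                          torque_sign = c("none", "+", "-")) {
  com_sign <- match.arg(com_sign)
  torque_sign <- match.arg(torque_sign)
  for (g in list(k_d, k_v, k_a, lambda_s)) {
    if (!is.numeric(g) || length(g) != 1L || !is.finite(g)) {
      stop("gains and delay must be single finite numbers", call. = FALSE)
    }
  }
  if (lambda_s < 0) stop("`lambda_s` must be >= 0", call. = FALSE)
  structure(
    list(k_d = unname(k_d), k_v = unname(k_v), k_a = unname(k_a),
         lambda_s = unname(lambda_s),
         com_sign = com_sign, torque_sign = torque_sign),
    class = "feedback_loop"
  )
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf(
    "<feedback_loop> com %s -> torque %s | k_d %.4g, k_v %.4g, k_a %.4g, lambda %.0f ms\n",
    x$com_sign, x$torque_sign, x$k_d, x$k_v, x$k_a, 1000 * x$lambda_s
  ))
  invisible(x)
}

# canonical gating of the four residual loops, in fixed order
residual_gatings <- function() {
  list(
    list(com_sign = "+", torque_sign = "+"),
    list(com_sign = "+", torque_sign = "-"),
    list(com_sign = "-", torque_sign = "+"),
    list(com_sign = "-", torque_sign = "-")
  )
}

#' Create a per-joint delayed CoM feedback model
#'
#' The full structure is one instantaneous acceleration loop (acceleration
#' gain and delay only, acting on the full-wave CoM acceleration) plus four
#' sign-gated residual loops, one per combination of CoM input half-wave
#' (positive/negative) and reconstructed torque sign (positive/negative).
#' With every gain in use the structure exposes 18 independent free
#' parameters: 2 for the acceleration loop and 4 loops x (3 gains + 1 delay).
#'
#' @param joint_id Joint label, e.g. `"ankle_pf"`, `"knee_flex"`,
#'   `"hip_flex"`, `"hip_add"`.
#' @param axis CoM input axis the model was built for: `"x"` (frontal) or
#'   `"y"` (sagittal).
#' @param accel_loop A `feedback_loop` with `com_sign = "both"`,
#'   `torque_sign = "none"` and zero displacement/velocity gains.
#' @param residual_loops List of exactly 4 `feedback_loop`s covering the four
#'   `com_sign` x `torque_sign` combinations (any order; stored canonically).
#' @param train_condition Optional provenance record (named list) of the
#'   condition the model was fitted on.
#'
#' @return An object of class `"com_feedback_model"`.
#' @export
com_feedback_model <- function(joint_id, axis,
                               accel_loop = feedback_loop(),
                               residual_loops = lapply(residual_gatings(), function(g) {
                                 feedback_loop(com_sign = g$com_sign, torque_sign = g$torque_sign)
                               }),
                               train_condition = NULL) {
  axis <- match.arg(axis, c("x", "y"))
  stopifnot(inherits(accel_loop, "feedback_loop"))
  if (accel_loop$com_sign != "both" || accel_loop$torque_sign != "none" ||
      accel_loop$k_d != 0 || accel_loop$k_v != 0) {
    stop("the acceleration loop must act on the full-wave input with k_d = k_v = 0",
         call. = FALSE)
  }
  if (length(residual_loops) != 4L ||
      !all(vapply(residual_loops, inherits, logical(1), what = "feedback_loop"))) {
    stop("`residual_loops` must be a list of 4 feedback_loop objects", call. = FALSE)
  }
  key <- vapply(residual_loops, function(l) paste0(l$com_sign, l$torque_sign), character(1))
  want <- vapply(residual_gatings(), function(g) paste0(g$com_sign, g$torque_sign), character(1))
  if (!setequal(key, want) || anyDuplicated(key)) {
    stop("residual loops must cover the four com_sign x torque_sign combinations",
         call. = FALSE)
  }
  residual_loops <- residual_loops[match(want, key)]
  structure(
    list(joint_id = joint_id, axis = axis, accel_loop = accel_loop,
         residual_loops = residual_loops, train_condition = train_condition),
    class = "com_feedback_model"
  )
}

#' @export
print.com_feedback_model <- function(x, ...) {
  cat(sprintf("<com_feedback_model> joint %s, axis %s, %d active parameters\n",
              x$joint_id, x$axis, count_active_parameters(x)))
  cat("  accel: "); print(x$accel_loop)
  for (l in x$residual_loops) { cat("  "); print(l) }
  invisible(x)
}

#' Torque contribution of a single feedback loop
#'
#' Evaluates the loop on a CoM state: each kinematic channel is half-wave
#' rectified according to the loop's `com_sign`, delayed by the loop delay
#' (rounded to the nearest sample, leading gap back-filled with the first
#' value), scaled by its gain and summed.
#'
#' @param loop A `feedback_loop`.
#' @param com A `com_state`.
#' @return The loop torque as a `time_series` (Nm).
#' @export
loop_output <- function(loop, com) {
  stopifnot(inherits(loop, "feedback_loop"), inherits(com, "com_state"))
  ref <- com$d
  out <- numeric(length(ref$values))
  gains <- c(d = loop$k_d, v = loop$k_v, a = loop$k_a)
  for (ch in names(gains)) {
    g <- gains[[ch]]
    if (g == 0) next
    s <- halfwave_select(com[[ch]]$values, loop$com_sign)
    s <- delay_signal(ts_like(ref, s), loop$lambda_s)$values
    out <- out + g * s
  }
  time_series(out, dt = ref$dt, t0 = ref$t0, units = "Nm")
}

#' Predict a joint torque trace from CoM kinematics
#'
#' Sums the acceleration loop output and the four residual loop outputs.
#' If both the model and the CoM state carry a non-missing axis label they
#' must agree.
#'
#' @param model A `com_feedback_model`.
#' @param com A `com_state`.
#' @return Predicted torque as a `time_series` (Nm).
#' @export
predict_torque <- function(model, com) {
  stopifnot(inherits(model, "com_feedback_model"), inherits(com, "com_state"))
  if (!is.na(com$axis) && com$axis != model$axis) {
    stop(sprintf("model is for axis '%s' but CoM state is axis '%s'",
                 model$axis, com$axis), call. = FALSE)
  }
  out <- loop_output(model$accel_loop, com)
  for (l in model$residual_loops) {
    out$values <- out$values + loop_output(l, com)$values
  }
  out
}

#' Count the free parameters a model actually uses
#'
#' For each loop with at least one nonzero gain, counts its nonzero gains
#' plus its delay; loops with all-zero gains contribute nothing. The full
#' structure with every gain nonzero counts 18; an acceleration-only model
#' counts 2.
#'
#' @param model A `com_feedback_model`.
#' @return Integer number of active parameters.
#' @export
count_active_parameters <- function(model) {
  stopifnot(inherits(model, "com_feedback_model"))
  n_loop <- function(l) {
    ng <- sum(c(l$k_d, l$k_v, l$k_a) != 0)
    if (ng > 0L) ng + 1L else 0L
  }
  sum(vapply(c(list(model$accel_loop), model$residual_loops), n_loop, integer(1)))
}

#' Serialize / restore a model as JSON
#'
#' Writes all gains, delays and gating labels plus the training-condition
#' provenance to a small JSON document, and reads it back.
#'
#' @param model A `com_feedback_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "com_feedback_model"))
  strip <- function(l) unclass(l)
  obj <- list(
    joint_id = model$joint_id, axis = model$axis,
    accel_loop = strip(model$accel_loop),
    residual_loops = lapply(model$residual_loops, strip),
    train_condition = model$train_condition
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  mk <- function(l) feedback_loop(l$k_d, l$k_v, l$k_a, l$lambda_s,
                                  com_sign = l$com_sign, torque_sign = l$torque_sign)
  com_feedback_model(
    joint_id = obj$joint_id, axis = obj$axis,
    accel_loop = mk(obj$accel_loop),
    residual_loops = lapply(obj$residual_loops, mk),
    train_condition = obj$train_condition
  )
}
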