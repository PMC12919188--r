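# Synthetic study generator: platform motion profiles (ramp-and-hold,
# sinusoid, sinusoid with superimposed perturbations), a closed-loop
# linearized inverted-pendulum plant stabilized by known ground-truth delayed
# CoM feedback models, and the full perturbation protocol (8 directions x 4
# magnitudes x 5 reps of ramps; 36 sinusoid-block trials).
#
# Direction convention used everywhere: 0 deg = rightward platform
# translation (+x, frontal axis), 90 deg = anterior (+y, sagittal axis).

#' Ramp-and-hold perturbation specification
#'
#' A support-surface translation with a symmetric trapezoidal velocity
#' profile: accelerate at `peak_acceleration_g` to `peak_velocity`, cruise,
#' decelerate to rest at `displacement`. Feasibility requires
#' `displacement >= peak_velocity^2 / (peak_acceleration_g * 9.81)`.
#'
#' @param displacement Total platform displacement (m).
#' @param peak_velocity Peak platform velocity (m/s).
#' @param peak_acceleration_g Peak platform acceleration in g units.
#' @param direction_deg Heading of the translation (deg).
#' @param label Magnitude label, e.g. `"small_slow"`.
#'
#' @return An object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(displacement, peak_velocity, peak_acceleration_g,
                              direction_deg = 0, label = "") {
  a <- peak_acceleration_g * 9.81
  if (displacement < 0 || peak_velocity <= 0 || a <= 0) {
    stop("displacement must be >= 0 and velocity/acceleration positive", call. = FALSE)
  }
  if (displacement > 0 && displacement < peak_velocity^2 / a - 1e-12) {
    stop("infeasible ramp: displacement < peak_velocity^2 / peak_acceleration",
         call. = FALSE)
  }
  structure(
    list(displacement = displacement, peak_velocity = peak_velocity,
         peak_acceleration_g = peak_acceleration_g,
         direction_deg = direction_deg, label = label),
    class = "perturbation_spec"
  )
}

#' The four ramp magnitudes of the study protocol
#'
#' `small_slow` (4.9 cm, 16 cm/s, 1.06 g), `small_fast` (4.9 cm, 24 cm/s,
#' 1.6 g), `medium` (7.7 cm, 16 cm/s, 1.06 g) and `large` (12.6 cm, 24 cm/s,
#' 1.6 g).
#'
#' @return Named list of `perturbation_spec`s.
#' @export
ramp_specs <- function() {
  list(
    small_slow = perturbation_spec(0.049, 0.16, 1.06, label = "small_slow"),
    small_fast = perturbation_spec(0.049, 0.24, 1.60, label = "small_fast"),
    medium     = perturbation_spec(0.077, 0.16, 1.06, label = "medium"),
    large      = perturbation_spec(0.126, 0.24, 1.60, label = "large")
  )
}

#' Sinusoidal platform motion specification
#'
#' Constant-frequency sinusoid along one plane with half-cycle cosine on/off
#' tapers (so the platform does not need an acceleration impulse at onset),
#' optionally with discrete ramp perturbations superimposed at displacement
#' zero crossings.
#'
#' @param amplitude Peak displacement (m); study value 0.077.
#' @param frequency_hz Frequency (Hz); study value 0.75.
#' @param cycles Number of cycles; study value 10.
#' @param plane `"sagittal"` (90-270 deg axis) or `"frontal"` (0-180 deg).
#' @param start_sign +1 to start moving toward the positive axis direction,
#'   -1 for the negative direction.
#' @param superimposed Optional data frame with one row per injected
#'   perturbation: `crossing` (zero-crossing index, 1-based), `label`
#'   (ramp magnitude label, `"small_slow"` or `"small_fast"`) and `class`
#'   (`"accelerating"` moves with the platform, `"braking"` against it).
#'
#' @return An object of class `"sinusoid_spec"`.
#' @export
sinusoid_spec <- function(amplitude = 0.077, frequency_hz = 0.75, cycles = 10,
                          plane = c("sagittal", "frontal"), start_sign = 1,
                          superimposed = NULL) {
  plane <- match.arg(plane)
  if (amplitude < 0 || frequency_hz <= 0 || cycles <= 0) {
    stop("amplitude must be >= 0 and frequency/cycles positive", call. = FALSE)
  }
  if (!start_sign %in% c(-1, 1)) stop("`start_sign` must be +1 or -1", call. = FALSE)
  if (!is.null(superimposed)) {
    stopifnot(is.data.frame(superimposed),
              all(c("crossing", "label", "class") %in% names(superimposed)))
  }
  structure(
    list(amplitude = amplitude, frequency_hz = frequency_hz, cycles = cycles,
         plane = plane, start_sign = start_sign, superimposed = superimposed),
    class = "sinusoid_spec"
  )
}

#' Generate a ramp-and-hold platform motion profile
#'
#' Produces position, velocity and acceleration evaluated analytically on the
#' sample grid (velocity and acceleration are the exact derivatives of the
#' position trajectory): accelerate at the peak acceleration to the peak
#' velocity, cruise, decelerate to rest, then hold the final displacement.
#'
#' @param spec A `perturbation_spec`.
#' @param dt Sample interval (s).
#' @param hold_s Hold time appended after the platform comes to rest (s).
#'
#' @return A list of `time_series`: `pos` (m), `vel` (m/s), `acc` (m/s^2),
#'   starting at `t = 0` (motion onset).
#' @export
make_ramp_profile <- function(spec, dt = 0.001, hold_s = 0.5) {
  stopifnot(inherits(spec, "perturbation_spec"))
  a <- spec$peak_acceleration_g * 9.81
  v <- spec$peak_velocity
  d <- spec$displacement
  if (d == 0) {
    n <- as.integer(round(hold_s / dt)) + 1L
    z <- numeric(n)
    return(list(pos = time_series(z, dt, 0, "m"),
                vel = time_series(z, dt, 0, "m/s"),
                acc = time_series(z, dt, 0, "m/s^2")))
  }
  t1 <- v / a                      # end of acceleration
  t_cruise <- (d - v^2 / a) / v    # constant-velocity duration
  t2 <- t1 + t_cruise              # start of deceleration
  t3 <- t2 + t1                    # platform at rest
  t <- seq(0, t3 + hold_s, by = dt)
  pos <- numeric(length(t)); vel <- numeric(length(t)); acc <- numeric(length(t))
  ph1 <- t <= t1
  pos[ph1] <- 0.5 * a * t[ph1]^2;            vel[ph1] <- a * t[ph1];       acc[ph1] <- a
  ph2 <- t > t1 & t <= t2
  pos[ph2] <- 0.5 * a * t1^2 + v * (t[ph2] - t1); vel[ph2] <- v;           acc[ph2] <- 0
  ph3 <- t > t2 & t <= t3
  pos[ph3] <- d - 0.5 * a * (t3 - t[ph3])^2; vel[ph3] <- a * (t3 - t[ph3]); acc[ph3] <- -a
  ph4 <- t > t3
  pos[ph4] <- d
  list(pos = time_series(pos, dt, 0, "m"),
       vel = time_series(vel, dt, 0, "m/s"),
       acc = time_series(acc, dt, 0, "m/s^2"))
}

# taper envelope and its first two derivatives at times t (half-cycle cosine
# on/off ramps inside the [0, L] span)
taper_envelope <- function(t, t_taper, total) {
  e <- rep(1, length(t)); e1 <- numeric(length(t)); e2 <- numeric(length(t))
  w <- pi / t_taper
  up <- t < t_taper
  e[up] <- 0.5 * (1 - cos(w * t[up]))
  e1[up] <- 0.5 * w * sin(w * t[up])
  e2[up] <- 0.5 * w^2 * cos(w * t[up])
  dn <- t > total - t_taper
  td <- total - t[dn]
  e[dn] <- 0.5 * (1 - cos(w * td))
  e1[dn] <- -0.5 * w * sin(w * td)
  e2[dn] <- 0.5 * w^2 * cos(w * td)
  out <- t < 0 | t > total
  e[out] <- 0; e1[out] <- 0; e2[out] <- 0
  list(e = e, e1 = e1, e2 = e2)
}

#' Generate a sinusoidal platform motion profile
#'
#' `A * sin(2 pi f t)` for the requested number of cycles with half-cycle
#' cosine on/off tapers (the taper scales the envelope, so displacement zero
#' crossings stay at `k / (2 f)`), with velocity and acceleration evaluated
#' analytically. Superimposed ramp perturbations listed in the spec are added
#' at their zero crossings with the sign implied by their class:
#' `"accelerating"` matches the platform velocity direction at the crossing,
#' `"braking"` opposes it.
#'
#' @param spec A `sinusoid_spec`.
#' @param dt Sample interval (s).
#' @param tail_s Quiet time appended after the last cycle (s).
#'
#' @return A list with `pos`, `vel`, `acc` (`time_series`, signed along the
#'   plane axis, starting at `t = 0`) and `injections`: a data frame with one
#'   row per superimposed perturbation (`onset_s`, `sign`, `label`, `class`),
#'   empty if none.
#' @export
make_sinusoid_profile <- function(spec, dt = 0.001, tail_s = 0.5) {
  stopifnot(inherits(spec, "sinusoid_spec"))
  f <- spec$frequency_hz
  A <- spec$amplitude * spec$start_sign
  L <- spec$cycles / f
  w <- 2 * pi * f
  t <- seq(0, L + tail_s, by = dt)
  env <- taper_envelope(t, t_taper = 1 / (2 * f), total = L)
  s <- sin(w * t); cst <- cos(w * t)
  inside <- t <= L
  s[!inside] <- 0; cst[!inside] <- 0
  pos <- A * env$e * s
  vel <- A * (env$e1 * s + env$e * w * cst)
  acc <- A * (env$e2 * s + 2 * env$e1 * w * cst - env$e * w^2 * s)

  injections <- data.frame(onset_s = numeric(0), sign = numeric(0),
                           label = character(0), class = character(0))
  if (!is.null(spec$superimposed) && nrow(spec$superimposed) > 0) {
    sup <- spec$superimposed
    specs <- ramp_specs()
    onsets <- sup$crossing / (2 * f)
    ord <- order(onsets)
    sup <- sup[ord, , drop = FALSE]
    onsets <- onsets[ord]
    prev_end <- -Inf
    for (i in seq_len(nrow(sup))) {
      rs <- specs[[sup$label[i]]]
      if (is.null(rs)) stop("unknown ramp label: ", sup$label[i], call. = FALSE)
      if (onsets[i] >= L) stop("superimposed crossing beyond the sinusoid span", call. = FALSE)
      # platform velocity direction at an interior zero crossing k is
      # start_sign * (-1)^k (derivative of sin changes sign each half cycle)
      vel_sign <- spec$start_sign * (-1)^(sup$crossing[i] %% 2)
      ramp_sign <- if (sup$class[i] == "accelerating") vel_sign else -vel_sign
      prof <- make_ramp_profile(rs, dt = dt, hold_s = 0)
      if (onsets[i] < prev_end) stop("overlapping superimposed perturbations", call. = FALSE)
      prev_end <- onsets[i] + ts_end(prof$pos)
      i0 <- as.integer(round(onsets[i] / dt)) + 1L
      ii <- i0:min(i0 + length(prof$pos$values) - 1L, length(t))
      src <- seq_along(ii)
      pos[ii] <- pos[ii] + ramp_sign * prof$pos$values[src]
      vel[ii] <- vel[ii] + ramp_sign * prof$vel$values[src]
      acc[ii] <- acc[ii] + ramp_sign * prof$acc$values[src]
      # the ramp leaves a net platform offset; carry it through the rest
      if (max(ii) < length(t)) {
        rest <- (max(ii) + 1L):length(t)
        pos[rest] <- pos[rest] + ramp_sign * rs$displacement
      }
      injections <- rbind(injections, data.frame(
        onset_s = onsets[i], sign = ramp_sign,
        label = sup$label[i], class = sup$class[i]
      ))
    }
  }
  list(pos = time_series(pos, dt, 0, "m"),
       vel = time_series(vel, dt, 0, "m/s"),
       acc = time_series(acc, dt, 0, "m/s^2"),
       injections = injections)
}
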