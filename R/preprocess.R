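# Turn raw per-trial recordings into the averaged, windowed,
# background-referenced responses the model is fit to: within-condition trial
# averaging, low-torque exclusion, perturbation-onset detection, and the
# sinusoid-residual extraction of superimposed-perturbation responses.

condition_key_of <- function(trial) {
  m <- trial$meta
  list(condition_label = m$condition_label %||% NA_character_,
       direction_deg = m$direction_deg %||% NA_real_,
       magnitude_label = m$magnitude_label %||% NA_character_,
       plane = m$plane %||% NA_character_,
       start_sign = m$start_sign %||% NA_real_)
}

same_key <- function(a, b) {
  eq <- function(x, y) (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && x == y)
  all(mapply(eq, a, b))
}

#' Average trials within one condition
#'
#' Pointwise per-channel mean of repeated trials of the same condition. All
#' trials must carry the same condition key (condition label, direction,
#' magnitude, plane, starting direction) and share the time base — i.e. they
#' have already been aligned on the perturbation onset (see
#' [truncate_window()]).
#'
#' @param trials List of `ts_trial`s (>= 1).
#' @param excluded_reps Optional record of repetitions left out upstream
#'   (list of reason strings), stored for reporting.
#'
#' @return An object of class `"condition_average"`: `trial` (the mean
#'   `ts_trial`), `n_trials`, `key` and `excluded_reps`.
#' @export
average_condition <- function(trials, excluded_reps = list()) {
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  stopifnot(all(vapply(trials, inherits, logical(1), what = "ts_trial")))
  key <- condition_key_of(trials[[1L]])
  for (tr in trials[-1L]) {
    if (!same_key(key, condition_key_of(tr))) {
      stop("trials have mixed condition keys; average within one condition",
           call. = FALSE)
    }
  }
  ref <- trials[[1L]]$channels[[1L]]
  nm <- names(trials[[1L]]$channels)
  for (tr in trials[-1L]) {
    ok <- identical(names(tr$channels), nm) &&
      length(tr$channels[[1L]]$values) == length(ref$values) &&
      isTRUE(all.equal(tr$channels[[1L]]$t0, ref$t0))
    if (!ok) stop("trials are not aligned on a shared time base", call. = FALSE)
  }
  channels <- lapply(nm, function(ch) {
    vals <- rowMeans(vapply(trials, function(tr) tr$channels[[ch]]$values,
                            numeric(length(ref$values))))
    time_series(vals, dt = ref$dt, t0 = ref$t0, units = trials[[1L]]$channels[[ch]]$units)
  })
  names(channels) <- nm
  meta <- trials[[1L]]$meta
  meta$rep_index <- NULL
  avg <- ts_trial(channels, meta)
  structure(list(trial = avg, n_trials = length(trials), key = key,
                 excluded_reps = excluded_reps),
            class = "condition_average")
}

#' @export
print.condition_average <- function(x, ...) {
  cat(sprintf("<condition_average> %s | n = %d trials%s\n",
              trial_key(x$trial), x$n_trials,
              if (length(x$excluded_reps)) sprintf(" (%d reps excluded)", length(x$excluded_reps)) else ""))
  invisible(x)
}

#' Low-torque exclusion rule
#'
#' A condition is excluded from analysis when the joint's torque range
#' (max minus min over the analysis window) is strictly less than the
#' threshold, reflecting a signal-to-noise ratio too low for meaningful
#' fitting. A range exactly at the threshold is retained.
#'
#' @param avg A `condition_average` (or `ts_trial`).
#' @param joint_id Joint label; the channel `tau_<joint_id>_Nm` is assessed.
#' @param threshold_nm Exclusion threshold in Nm (default 10).
#'
#' @return `TRUE` if the condition should be excluded.
#' @export
exclude_low_torque <- function(avg, joint_id, threshold_nm = 10) {
  trial <- if (inherits(avg, "condition_average")) avg$trial else avg
  tau <- trial_channel(trial, sprintf("tau_%s_Nm", joint_id))
  diff(range(tau$values)) < threshold_nm
}

#' Detect perturbation onset from platform acceleration
#'
#' Returns the first time at which the platform acceleration magnitude
#' exceeds `threshold` continuously for `sustain_s`. Synthetic trials carry
#' ground-truth onsets in their metadata; this detector exists for external
#' recordings without one.
#'
#' @param trial A `ts_trial` with platform acceleration channels.
#' @param threshold Acceleration threshold (m/s^2).
#' @param sustain_s Minimum time the threshold must stay exceeded (s).
#'
#' @return Onset time (s), or an error if no crossing is found.
#' @export
detect_onset <- function(trial, threshold = 0.05, sustain_s = 0.010) {
  ax <- trial_channel(trial, "plat_acc_x_mps2")$values
  ay <- trial_channel(trial, "plat_acc_y_mps2")$values
  mag <- sqrt(ax^2 + ay^2)
  dt <- trial$channels[[1L]]$dt
  need <- max(1L, as.integer(round(sustain_s / dt)))
  above <- mag > threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) {
      return(trial$channels[[1L]]$t0 + (i - run) * dt)
    }
  }
  stop("no sustained platform acceleration above threshold", call. = FALSE)
}

# direction of platform motion of a plane's sinusoid at time t, from the
# average's platform velocity channel: returns the signed axis heading (deg)
sinusoid_heading_at <- function(avg_trial, plane, t) {
  ax <- plane_axis(plane)
  vel <- trial_channel(avg_trial, sprintf("plat_vel_%s_mps", ax))
  v <- vel$values[ts_index(vel, t)]
  base <- if (ax == "x") 0 else 90
  if (v >= 0) base else (base + 180) %% 360
}

#' Extract superimposed-perturbation responses from a sinusoid trial
#'
#' Subtracts the average response to the perturbation-free sinusoid from a
#' sinusoid trial with superimposed perturbations (channel by channel, after
#' verifying the two are phase-aligned), segments the residual at each
#' superimposed-perturbation onset from the trial metadata, classifies each
#' segment as `"accelerating"` (perturbation along the platform's motion at
#' the zero crossing) or `"braking"` (opposing it), re-bases each segment so
#' its onset is `t = 0`, and truncates to `[-pre_s, +post_s]`.
#'
#' @param pert_trial A `ts_trial` with `condition_label
#'   "sinusoid_perturbed"` and a `meta$superimposed` table.
#' @param sinusoid_only_avg A `condition_average` of perturbation-free
#'   sinusoid trials of the same plane and starting direction, on the same
#'   time base.
#' @param pre_s,post_s Segment window around each onset (s).
#' @param max_lag_s Phase-alignment tolerance: if the platform-position
#'   cross-correlation between trial and average peaks at a lag larger than
#'   this, the pair is rejected.
#'
#' @return List of `ts_trial` segments with `condition_label
#'   "superimposed"`, carrying `direction_deg`, `magnitude_label` and
#'   `class` metadata.
#' @export
extract_superimposed_response <- function(pert_trial, sinusoid_only_avg,
                                          pre_s = 0.25, post_s = 1.0,
                                          max_lag_s = 0.001) {
  stopifnot(inherits(pert_trial, "ts_trial"),
            inherits(sinusoid_only_avg, "condition_average"))
  avg <- sinusoid_only_avg$trial
  sup <- pert_trial$meta$superimposed
  if (is.null(sup) || nrow(sup) == 0) {
    stop("trial carries no superimposed-perturbation metadata", call. = FALSE)
  }
  plane <- pert_trial$meta$plane
  if (is.null(plane) || !identical(plane, avg$meta$plane) ||
      !identical(pert_trial$meta$start_sign, avg$meta$start_sign)) {
    stop("trial and sinusoid average must share plane and starting direction",
         call. = FALSE)
  }
  ref <- pert_trial$channels[[1L]]
  aref <- avg$channels[[1L]]
  n <- min(length(ref$values), length(aref$values))
  if (abs(ref$t0 - aref$t0) > ref$dt / 2) {
    stop("trial and average are not on the same time base", call. = FALSE)
  }

  # phase check on the plane's platform position, over the span before the
  # first injected perturbation (injections add net platform offsets). With a
  # known sinusoid frequency the lag comes from a coherent phase projection,
  # which is far less noise-sensitive than the discrete cross-correlation
  # peak; otherwise the ccf peak is used.
  ax <- plane_axis(plane)
  n_check <- min(n, ts_index(ref, min(sup$onset_s)) - 1L)
  if (n_check < as.integer(round(1 / ref$dt))) n_check <- n
  p1 <- trial_channel(pert_trial, sprintf("plat_pos_%s_m", ax))$values[seq_len(n_check)]
  p0 <- trial_channel(avg, sprintf("plat_pos_%s_m", ax))$values[seq_len(n_check)]
  f <- pert_trial$meta$frequency_hz
  if (!is.null(f) && is.finite(f) && f > 0) {
    tt <- (seq_len(n_check) - 1L) * ref$dt
    B <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    BtB <- crossprod(B)
    phase_of <- function(v) {
      co <- solve(BtB, crossprod(B, v))
      atan2(co[2L], co[1L])
    }
    dphi <- (phase_of(p1) - phase_of(p0) + pi) %% (2 * pi) - pi
    lag_s <- dphi / (2 * pi * f)
  } else {
    max_lag <- max(1L, as.integer(round(0.25 / ref$dt)))
    cc <- stats::ccf(p1, p0, lag.max = max_lag, plot = FALSE)
    lag_s <- cc$lag[which.max(cc$acf)] * ref$dt
  }
  if (abs(lag_s) > max_lag_s + 1e-12) {
    stop(sprintf("phase mismatch between trial and sinusoid average (lag %.1f ms)",
                 1000 * lag_s), call. = FALSE)
  }

  diff_channels <- lapply(names(pert_trial$channels), function(ch) {
    time_series(pert_trial$channels[[ch]]$values[seq_len(n)] -
                  avg$channels[[ch]]$values[seq_len(n)],
                dt = ref$dt, t0 = ref$t0,
                units = pert_trial$channels[[ch]]$units)
  })
  names(diff_channels) <- names(pert_trial$channels)

  segments <- vector("list", nrow(sup))
  for (i in seq_len(nrow(sup))) {
    heading <- sinusoid_heading_at(avg, plane, sup$onset_s[i])
    klass <- if (isTRUE(all.equal(heading, sup$direction_deg[i] %% 360))) {
      "accelerating"
    } else "braking"
    meta <- list(participant_id = pert_trial$meta$participant_id,
                 mass_kg = pert_trial$meta$mass_kg,
                 condition_label = "superimposed",
                 direction_deg = sup$direction_deg[i],
                 magnitude_label = sup$magnitude_label[i],
                 plane = plane, start_sign = pert_trial$meta$start_sign,
                 class = klass, onset_s = sup$onset_s[i],
                 rep_index = pert_trial$meta$rep_index)
    seg <- ts_trial(diff_channels, meta)
    segments[[i]] <- truncate_window(seg, pre_s, post_s)
  }
  segments
}
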