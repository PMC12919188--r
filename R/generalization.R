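# The four transfer protocols: models are trained on cardinal-direction
# ramp-and-hold averages and evaluated (1) on diagonal directions via
# quadrant-matched per-axis summation, (2) across ramp magnitudes, (3) on
# continuous sinusoidal platform motion, and (4) on discrete perturbations
# superimposed on the sinusoid, plus the mean +/- SD report tables.

JOINTS <- c("ankle_pf", "knee_flex", "hip_flex", "hip_add")
CARDINALS <- c(0, 90, 180, 270)
DIAGONALS <- c(45, 135, 225, 315)

#' Cardinal source directions for a diagonal perturbation
#'
#' Diagonal-direction torque is predicted from models trained on the two
#' cardinal directions bounding the diagonal's quadrant: the frontal (x)
#' source is the nearest of 0/180 deg and the sagittal (y) source the
#' nearest of 90/270 deg, so left/right and forward/backward asymmetries are
#' preserved (e.g. 135 deg uses the 180 deg and 90 deg models).
#'
#' @param direction_deg A diagonal direction: 45, 135, 225 or 315.
#' @return Named numeric vector with elements `x` and `y` (deg).
#' @export
quadrant_sources <- function(direction_deg) {
  if (!direction_deg %in% DIAGONALS) {
    stop("`direction_deg` must be a diagonal direction (45, 135, 225, 315)",
         call. = FALSE)
  }
  x_source <- if (cospi(direction_deg / 180) > 0) 0 else 180
  y_source <- if (sinpi(direction_deg / 180) > 0) 90 else 270
  c(x = x_source, y = y_source)
}

#' Predict diagonal-direction torque from two cardinal-trained models
#'
#' Per-axis superposition: the prediction is the frontal-axis model applied
#' to the frontal CoM state plus the sagittal-axis model applied to the
#' sagittal CoM state. A joint modelled on a single axis (e.g. hip adduction
#' in the frontal plane) may pass `NULL` for the missing axis, whose term
#' then contributes zero; passing `NULL` for both is an error.
#'
#' @param model_x,model_y `com_feedback_model`s trained at the quadrant's
#'   cardinal directions (or `NULL`).
#' @param com_x,com_y `com_state`s of the diagonal trial, axes x and y.
#' @return Predicted torque `time_series`.
#' @export
predict_diagonal <- function(model_x, model_y, com_x, com_y) {
  if (is.null(model_x) && is.null(model_y)) {
    stop("no model available on either axis", call. = FALSE)
  }
  out <- NULL
  if (!is.null(model_x)) out <- predict_torque(model_x, com_x)
  if (!is.null(model_y)) {
    py <- predict_torque(model_y, com_y)
    out <- if (is.null(out)) py else ts_like(out, out$values + py$values)
  }
  out
}

# -- shared helpers ----------------------------------------------------------

ramp_trials_of <- function(study, direction_deg, magnitude_label) {
  sel <- study$manifest$condition_label == "ramp" &
    study$manifest$direction_deg == direction_deg &
    study$manifest$magnitude_label == magnitude_label
  study$trials[study$manifest$trial_id[sel]]
}

# averaged, truncated ramp response for one condition
ramp_average <- function(study, direction_deg, magnitude_label,
                         pre_s = 0.25, post_s = 1.0) {
  trials <- ramp_trials_of(study, direction_deg, magnitude_label)
  if (length(trials) == 0L) return(NULL)
  average_condition(lapply(trials, truncate_window, pre_s = pre_s, post_s = post_s))
}

# background-subtracted torque channel of an averaged trial (onset at 0)
avg_torque <- function(avg, joint, background_window_s = 0.25) {
  tau <- trial_channel(avg$trial, sprintf("tau_%s_Nm", joint))
  remove_background_torque(tau, 0, background_window_s)$trace
}

result_row <- function(protocol, phase, joint, r2 = NA_real_,
                       rmse_per_kg = NA_real_, excluded = FALSE,
                       train_direction_deg = NA_real_, test_direction_deg = NA_real_,
                       train_magnitude = NA_character_, test_magnitude = NA_character_,
                       context = NA_character_, plane = NA_character_,
                       participant_id = NA_character_, n_trials = NA_integer_) {
  data.frame(protocol = protocol, phase = phase, joint = joint,
             train_direction_deg = train_direction_deg,
             test_direction_deg = test_direction_deg,
             train_magnitude = train_magnitude, test_magnitude = test_magnitude,
             context = context, plane = plane,
             r2 = r2, rmse_per_kg = rmse_per_kg, excluded = excluded,
             participant_id = participant_id, n_trials = n_trials,
             stringsAsFactors = FALSE)
}

#' Fit cardinal-direction ramp models for a study
#'
#' Fits one delayed CoM feedback model per (magnitude, cardinal direction,
#' joint) cell on the averaged, background-subtracted ramp response, with
#' the sagittal CoM state driving fits at 90/270 deg and the frontal CoM
#' state at 0/180 deg. Cells whose averaged torque range falls below the
#' exclusion threshold are skipped.
#'
#' @param study A `com_study`.
#' @param cfg A [fit_config()].
#' @param magnitudes,directions,joints Cells to fit (defaults: every
#'   magnitude present, all four cardinals, all four joints).
#' @param exclude_threshold_nm Low-torque exclusion threshold (Nm).
#'
#' @return Nested list `fits[[magnitude]][[direction]][[joint]]` of
#'   `fit_result` (absent where excluded), with the condition averages in
#'   `attr(, "averages")`.
#' @export
fit_ramp_models <- function(study, cfg = fit_config(),
                            magnitudes = NULL, directions = CARDINALS,
                            joints = JOINTS, exclude_threshold_nm = 10) {
  stopifnot(inherits(study, "com_study"))
  if (is.null(magnitudes)) {
    magnitudes <- unique(stats::na.omit(study$manifest$magnitude_label[
      study$manifest$condition_label == "ramp"]))
  }
  fits <- list()
  avgs <- list()
  for (mag in magnitudes) {
    fits[[mag]] <- list()
    avgs[[mag]] <- list()
    for (dir in directions) {
      avg <- ramp_average(study, dir, mag)
      if (is.null(avg)) next
      avgs[[mag]][[as.character(dir)]] <- avg
      axis <- axis_of_direction(dir)
      com <- com_state_from_trial(avg$trial, axis)
      cell <- list()
      for (joint in joints) {
        if (exclude_low_torque(avg, joint, exclude_threshold_nm)) next
        tau <- avg_torque(avg, joint, cfg$background_window_s)
        fr <- fit_model(com, tau, cfg, mass_kg = avg$trial$meta$mass_kg)
        fr$model$joint_id <- joint
        fr$model$train_condition <- list(direction_deg = dir, magnitude_label = mag,
                                         condition_label = "ramp")
        cell[[joint]] <- fr
      }
      fits[[mag]][[as.character(dir)]] <- cell
    }
  }
  attr(fits, "averages") <- avgs
  fits
}

# look up a fitted model (NULL when the cell was excluded or absent)
fitted_model <- function(fits, magnitude, direction, joint) {
  fr <- fits[[magnitude]][[as.character(direction)]][[joint]]
  if (is.null(fr)) NULL else fr$model
}

# -- protocol 1: direction ---------------------------------------------------

#' Direction-generalization protocol
#'
#' Trains per-joint models on the four cardinal directions (per magnitude)
#' and tests them on the four diagonals via [predict_diagonal()] with
#' quadrant-matched sources. Trained-condition metrics come from the fits
#' themselves; tested-condition metrics compare the summed cardinal
#' prediction with the averaged diagonal response.
#'
#' @inheritParams fit_ramp_models
#' @param fits Optional precomputed [fit_ramp_models()] result.
#' @return Data frame of per-cell results (`phase` is `"trained"` or
#'   `"tested"`; excluded cells carry no metrics).
#' @export
run_direction_generalization <- function(study, cfg = fit_config(),
                                         magnitudes = NULL, joints = JOINTS,
                                         exclude_threshold_nm = 10,
                                         fits = NULL) {
  if (is.null(fits)) {
    fits <- fit_ramp_models(study, cfg, magnitudes = magnitudes, joints = joints,
                            exclude_threshold_nm = exclude_threshold_nm)
  }
  pid <- study$trials[[1L]]$meta$participant_id %||% NA_character_
  rows <- list()
  for (mag in names(fits)) {
    for (dir in names(fits[[mag]])) {
      for (joint in joints) {
        fr <- fits[[mag]][[dir]][[joint]]
        rows[[length(rows) + 1L]] <- if (is.null(fr)) {
          result_row("direction", "trained", joint, excluded = TRUE,
                     train_direction_deg = as.numeric(dir), train_magnitude = mag,
                     participant_id = pid)
        } else {
          result_row("direction", "trained", joint,
                     r2 = fr$r2_train, rmse_per_kg = fr$rmse_per_kg_train,
                     train_direction_deg = as.numeric(dir), train_magnitude = mag,
                     participant_id = pid)
        }
      }
    }
    for (dir in DIAGONALS) {
      avg <- ramp_average(study, dir, mag)
      if (is.null(avg)) next
      src <- quadrant_sources(dir)
      com_x <- com_state_from_trial(avg$trial, "x")
      com_y <- com_state_from_trial(avg$trial, "y")
      for (joint in joints) {
        if (exclude_low_torque(avg, joint, exclude_threshold_nm)) {
          rows[[length(rows) + 1L]] <- result_row(
            "direction", "tested", joint, excluded = TRUE,
            test_direction_deg = dir, train_magnitude = mag, test_magnitude = mag,
            participant_id = pid)
          next
        }
        model_x <- fitted_model(fits, mag, src[["x"]], joint)
        model_y <- fitted_model(fits, mag, src[["y"]], joint)
        if (is.null(model_x) && is.null(model_y)) {
          rows[[length(rows) + 1L]] <- result_row(
            "direction", "tested", joint, excluded = TRUE,
            test_direction_deg = dir, train_magnitude = mag, test_magnitude = mag,
            participant_id = pid)
          next
        }
        tau <- avg_torque(avg, joint, cfg$background_window_s)
        pred <- predict_diagonal(model_x, model_y, com_x, com_y)
        rows[[length(rows) + 1L]] <- result_row(
          "direction", "tested", joint,
          r2 = compute_r2(tau, pred),
          rmse_per_kg = compute_rmse_per_kg(tau, pred, avg$trial$meta$mass_kg),
          test_direction_deg = dir, train_magnitude = mag, test_magnitude = mag,
          participant_id = pid, n_trials = avg$n_trials)
      }
    }
  }
  do.call(rbind, rows)
}

# -- protocol 2: magnitude ---------------------------------------------------

#' Magnitude-generalization protocol
#'
#' Uses the gains and delays fitted at one ramp magnitude to predict the
#' response at every other magnitude, cardinal directions only, with models
#' matched to the perturbation direction. The train = test diagonal of the
#' matrix reproduces the training metrics and is reported with `phase
#' "trained"`.
#'
#' @inheritParams run_direction_generalization
#' @return Data frame of per-cell results.
#' @export
run_magnitude_generalization <- function(study, cfg = fit_config(),
                                         magnitudes = NULL, joints = JOINTS,
                                         exclude_threshold_nm = 10,
                                         fits = NULL) {
  if (is.null(fits)) {
    fits <- fit_ramp_models(study, cfg, magnitudes = magnitudes, joints = joints,
                            exclude_threshold_nm = exclude_threshold_nm)
  }
  pid <- study$trials[[1L]]$meta$participant_id %||% NA_character_
  avgs <- attr(fits, "averages")
  rows <- list()
  for (train_mag in names(fits)) {
    for (dir in names(fits[[train_mag]])) {
      axis <- axis_of_direction(as.numeric(dir))
      for (test_mag in names(fits)) {
        avg <- avgs[[test_mag]][[dir]]
        if (is.null(avg)) next
        com <- com_state_from_trial(avg$trial, axis)
        for (joint in joints) {
          fr <- fits[[train_mag]][[dir]][[joint]]
          phase <- if (train_mag == test_mag) "trained" else "tested"
          if (is.null(fr) || exclude_low_torque(avg, joint, exclude_threshold_nm)) {
            rows[[length(rows) + 1L]] <- result_row(
              "magnitude", phase, joint, excluded = TRUE,
              train_direction_deg = as.numeric(dir), test_direction_deg = as.numeric(dir),
              train_magnitude = train_mag, test_magnitude = test_mag,
              participant_id = pid)
            next
          }
          tau <- avg_torque(avg, joint, cfg$background_window_s)
          pred <- predict_torque(fr$model, com)
          rows[[length(rows) + 1L]] <- result_row(
            "magnitude", phase, joint,
            r2 = compute_r2(tau, pred),
            rmse_per_kg = compute_rmse_per_kg(tau, pred, avg$trial$meta$mass_kg),
            train_direction_deg = as.numeric(dir), test_direction_deg = as.numeric(dir),
            train_magnitude = train_mag, test_magnitude = test_mag,
            participant_id = pid, n_trials = avg$n_trials)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# -- protocols 3 & 4: movement context ---------------------------------------

sinusoid_trials_of <- function(study, plane, start_sign, label) {
  sel <- study$manifest$condition_label == label &
    !is.na(study$manifest$plane) & study$manifest$plane == plane &
    study$manifest$start_sign == start_sign
  if (label == "sinusoid_perturbed") {
    return(study$trials[study$manifest$trial_id[sel]])
  }
  study$trials[study$manifest$trial_id[sel]]
}

# direction whose ramp-trained gains are matched to a sinusoid plane/start
matched_direction <- function(plane, start_sign) {
  base <- if (plane == "frontal") 0 else 90
  if (start_sign >= 0) base else (base + 180) %% 360
}

#' Movement-context generalization protocols
#'
#' Evaluates ramp-trained models in a different movement context. For
#' `context = "sinusoid"`, predicts the averaged response to the
#' perturbation-free sinusoid over `[-0.25, +15]` s around platform onset,
#' with gains matched to the plane's cardinal direction (by starting
#' direction). For `context = "superimposed_slow"` / `"superimposed_fast"`,
#' extracts the residual responses to the discrete perturbations
#' superimposed on the sinusoid ([extract_superimposed_response()]),
#' averages them per perturbation direction, and predicts each with the
#' ramp-trained model matched to the perturbation direction, regardless of
#' the background sinusoid.
#'
#' @inheritParams run_direction_generalization
#' @param context `"sinusoid"`, `"superimposed_slow"` or
#'   `"superimposed_fast"`.
#' @param sinusoid_window_s Post-onset span of the sinusoid evaluation
#'   window (s).
#' @return Data frame of per-cell results, one row per (plane/direction,
#'   joint, training magnitude).
#' @export
run_context_generalization <- function(study, cfg = fit_config(),
                                       context = c("sinusoid", "superimposed_slow",
                                                   "superimposed_fast"),
                                       magnitudes = NULL, joints = JOINTS,
                                       exclude_threshold_nm = 10,
                                       sinusoid_window_s = 15,
                                       fits = NULL) {
  context <- match.arg(context)
  if (is.null(fits)) {
    fits <- fit_ramp_models(study, cfg, magnitudes = magnitudes, joints = joints,
                            exclude_threshold_nm = exclude_threshold_nm)
  }
  pid <- study$trials[[1L]]$meta$participant_id %||% NA_character_
  rows <- list()

  if (context == "sinusoid") {
    for (plane in c("sagittal", "frontal")) {
      for (ss in c(1, -1)) {
        trials <- sinusoid_trials_of(study, plane, ss, "sinusoid")
        if (length(trials) == 0L) next
        post <- min(sinusoid_window_s,
                    ts_end(trials[[1L]]$channels[[1L]]) - trials[[1L]]$meta$onset_s)
        avg <- average_condition(lapply(trials, truncate_window,
                                        pre_s = 0.25, post_s = post))
        dir <- matched_direction(plane, ss)
        axis <- plane_axis(plane)
        com <- com_state_from_trial(avg$trial, axis)
        for (train_mag in names(fits)) {
          for (joint in joints) {
            fr <- fits[[train_mag]][[as.character(dir)]][[joint]]
            if (is.null(fr) || exclude_low_torque(avg, joint, exclude_threshold_nm)) {
              rows[[length(rows) + 1L]] <- result_row(
                "sinusoid", "tested", joint, excluded = TRUE,
                train_direction_deg = dir, train_magnitude = train_mag,
                context = context, plane = plane, participant_id = pid)
              next
            }
            tau <- avg_torque(avg, joint, cfg$background_window_s)
            pred <- predict_torque(fr$model, com)
            rows[[length(rows) + 1L]] <- result_row(
              "sinusoid", "tested", joint,
              r2 = compute_r2(tau, pred),
              rmse_per_kg = compute_rmse_per_kg(tau, pred, avg$trial$meta$mass_kg),
              train_direction_deg = dir, train_magnitude = train_mag,
              context = context, plane = plane,
              participant_id = pid, n_trials = avg$n_trials)
          }
        }
      }
    }
    return(do.call(rbind, rows))
  }

  # superimposed contexts: gather residual segments across planes/starts
  want_label <- if (context == "superimposed_slow") "small_slow" else "small_fast"
  segments <- list()
  for (plane in c("sagittal", "frontal")) {
    for (ss in c(1, -1)) {
      base_trials <- sinusoid_trials_of(study, plane, ss, "sinusoid")
      pert_trials <- sinusoid_trials_of(study, plane, ss, "sinusoid_perturbed")
      pert_trials <- Filter(function(tr) {
        identical(tr$meta$magnitude_label, want_label)
      }, pert_trials)
      if (length(base_trials) == 0L || length(pert_trials) == 0L) next
      base_avg <- average_condition(base_trials)
      for (tr in pert_trials) {
        segs <- extract_superimposed_response(tr, base_avg)
        segments <- c(segments, segs)
      }
    }
  }
  if (length(segments) == 0L) return(NULL)

  seg_dirs <- vapply(segments, function(s) s$meta$direction_deg, numeric(1))
  for (dir in sort(unique(seg_dirs))) {
    group <- segments[seg_dirs == dir]
    # responses are pooled over the background sinusoid (starting direction
    # and accelerating/braking class), per the direction-matched transfer rule
    group <- lapply(group, function(s) {
      s$meta$start_sign <- NA_real_
      s$meta$class <- NULL
      s
    })
    avg <- average_condition(group)
    axis <- axis_of_direction(dir)
    com <- com_state_from_trial(avg$trial, axis)
    for (train_mag in names(fits)) {
      for (joint in joints) {
        fr <- fits[[train_mag]][[as.character(dir)]][[joint]]
        if (is.null(fr) || exclude_low_torque(avg, joint, exclude_threshold_nm)) {
          rows[[length(rows) + 1L]] <- result_row(
            "superimposed", "tested", joint, excluded = TRUE,
            train_direction_deg = dir, test_direction_deg = dir,
            train_magnitude = train_mag, test_magnitude = want_label,
            context = context, participant_id = pid)
          next
        }
        tau <- avg_torque(avg, joint, cfg$background_window_s)
        pred <- predict_torque(fr$model, com)
        rows[[length(rows) + 1L]] <- result_row(
          "superimposed", "tested", joint,
          r2 = compute_r2(tau, pred),
          rmse_per_kg = compute_rmse_per_kg(tau, pred, avg$trial$meta$mass_kg),
          train_direction_deg = dir, test_direction_deg = dir,
          train_magnitude = train_mag, test_magnitude = want_label,
          context = context, participant_id = pid, n_trials = avg$n_trials)
      }
    }
  }
  do.call(rbind, rows)
}

# -- reporting ---------------------------------------------------------------

#' Aggregate transfer results into mean +/- SD tables
#'
#' Groups result rows by protocol, phase, context and joint; reports the
#' mean and sample standard deviation (n - 1) of R^2 and RMSE/kg over
#' unexcluded cells, the cell count, and a good-fit flag (mean R^2 above
#' `r2_good` and mean RMSE below `rmse_good`). Cells with every contributing
#' result excluded are reported as excluded rather than as zero.
#'
#' @param results Data frame from the `run_*_generalization()` functions
#'   (rows from several runs/participants may be concatenated).
#' @param r2_good,rmse_good Good-fit thresholds (defaults 0.7 and 0.2 Nm/kg).
#' @return Data frame with one row per (protocol, phase, context, joint).
#' @export
aggregate_report <- function(results, r2_good = 0.7, rmse_good = 0.2) {
  stopifnot(is.data.frame(results))
  key <- interaction(results$protocol, results$phase,
                     ifelse(is.na(results$context), "", results$context),
                     results$joint, drop = TRUE)
  rows <- lapply(split(results, key), function(grp) {
    use <- grp[!grp$excluded, , drop = FALSE]
    n <- nrow(use)
    out <- data.frame(protocol = grp$protocol[1L], phase = grp$phase[1L],
                      context = grp$context[1L], joint = grp$joint[1L],
                      n = n, n_excluded = sum(grp$excluded),
                      r2_mean = NA_real_, r2_sd = NA_real_,
                      rmse_mean = NA_real_, rmse_sd = NA_real_,
                      good_fit = NA, stringsAsFactors = FALSE)
    if (n > 0) {
      out$r2_mean <- mean(use$r2)
      out$r2_sd <- if (n > 1) stats::sd(use$r2) else 0
      out$rmse_mean <- mean(use$rmse_per_kg)
      out$rmse_sd <- if (n > 1) stats::sd(use$rmse_per_kg) else 0
      out$good_fit <- out$r2_mean > r2_good && out$rmse_mean < rmse_good
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protocol, out$phase, out$context, match(out$joint, JOINTS)), ]
}

#' Render an aggregate report as aligned text
#'
#' @param report Data frame from [aggregate_report()].
#' @return Character vector of formatted lines (invisibly printed).
#' @export
format_report <- function(report) {
  lines <- sprintf("%-12s %-8s %-18s %-10s %15s %18s %6s",
                   "protocol", "phase", "context", "joint",
                   "R2 (mean+/-SD)", "RMSE Nm/kg", "good")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "%-12s %-8s %-18s %-10s %6.2f +/- %5.2f %9.3f +/- %5.3f %6s",
      r$protocol, r$phase, ifelse(is.na(r$context), "-", r$context), r$joint,
      r$r2_mean, r$r2_sd, r$rmse_mean, r$rmse_sd,
      ifelse(is.na(r$good_fit), "excl", ifelse(r$good_fit, "yes", "no"))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
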