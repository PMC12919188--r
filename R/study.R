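# Full study protocol: 8 directions x 4 magnitudes x 5 reps of ramp-and-hold
# trials (160), plus a sinusoid block of 2 planes x {none, slow, fast}
# superimposed-perturbation contexts x 6 reps (3 starts per direction), 36
# trials.

axis_of_direction <- function(direction_deg) {
  if (direction_deg %% 180 == 0) "x" else if (direction_deg %% 180 == 90) "y"
  else NA_character_
}

plane_axis <- function(plane) if (plane == "frontal") "x" else "y"

#' Enumerate the study protocol
#'
#' Builds the trial manifest of the full protocol without simulating:
#' ramp-and-hold trials over all direction x magnitude x repetition cells and
#' the sinusoid block over plane x superimposed-context x repetition cells.
#'
#' @param directions_deg Ramp directions (deg).
#' @param magnitudes Ramp magnitude labels (subset of `names(ramp_specs())`).
#' @param ramp_reps Repetitions per ramp condition.
#' @param sinusoid_reps Repetitions per sinusoid condition (alternating
#'   starting direction).
#' @param sinusoid_contexts Superimposed-perturbation contexts for the
#'   sinusoid block: subset of `c("none", "slow", "fast")`.
#'
#' @return A data frame with one row per trial: `trial_id`,
#'   `condition_label`, `direction_deg`, `magnitude_label`, `plane`,
#'   `start_sign`, `rep_index`.
#' @export
study_manifest <- function(directions_deg = seq(0, 315, by = 45),
                           magnitudes = names(ramp_specs()),
                           ramp_reps = 5,
                           sinusoid_reps = 6,
                           sinusoid_contexts = c("none", "slow", "fast")) {
  ramp <- expand.grid(rep_index = seq_len(ramp_reps),
                      magnitude_label = magnitudes,
                      direction_deg = directions_deg,
                      stringsAsFactors = FALSE)
  ramp <- data.frame(condition_label = rep("ramp", nrow(ramp)),
                     direction_deg = ramp$direction_deg,
                     magnitude_label = ramp$magnitude_label,
                     plane = rep(NA_character_, nrow(ramp)),
                     start_sign = rep(NA_real_, nrow(ramp)),
                     rep_index = ramp$rep_index,
                     stringsAsFactors = FALSE)
  sin_block <- expand.grid(rep_index = seq_len(sinusoid_reps),
                           context = sinusoid_contexts,
                           plane = c("sagittal", "frontal"),
                           stringsAsFactors = FALSE)
  sin_block <- data.frame(
    condition_label = ifelse(sin_block$context == "none", "sinusoid", "sinusoid_perturbed"),
    direction_deg = rep(NA_real_, nrow(sin_block)),
    magnitude_label = ifelse(sin_block$context == "none", NA_character_,
                             paste0("small_", sin_block$context)),
    plane = sin_block$plane,
    start_sign = ifelse(sin_block$rep_index %% 2 == 1, 1, -1),
    rep_index = sin_block$rep_index,
    stringsAsFactors = FALSE
  )
  out <- rbind(ramp, sin_block)
  if (nrow(out) == 0L) stop("empty protocol: no trials requested", call. = FALSE)
  out <- cbind(trial_id = sprintf("trial_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

#' Generate a full synthetic perturbation study
#'
#' Simulates every trial of the protocol in closed loop with the plant's
#' ground-truth feedback models and seeded measurement noise. Ramp trials run
#' 2 s (motion onset at 0.5 s); sinusoid-block trials run the 10-cycle
#' sinusoid with a 0.5 s lead-in. Sinusoid trials with superimposed
#' perturbations inject the discrete ramp at displacement zero crossings 5, 9
#' and 13, alternating accelerating and braking classes across repetitions.
#'
#' @param plant A [plant_params()].
#' @param seed Integer seed; every trial's measurement noise derives from it.
#' @param participant_id Identifier stored in each trial's metadata.
#' @param dt Sample interval (s); the study protocol records at 1 kHz.
#' @param ... Passed to [study_manifest()] to restrict the protocol (e.g.
#'   `magnitudes`, `directions_deg`, `ramp_reps`).
#'
#' @return An object of class `"com_study"`: a list with `trials` (named list
#'   of `ts_trial`), `manifest` (the protocol data frame with an `onset_s`
#'   column added), `plant` and `seed`.
#' @export
generate_study <- function(plant = plant_params(), seed = 1L,
                           participant_id = "S01", dt = 0.001, ...) {
  manifest <- study_manifest(...)
  n <- nrow(manifest)
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  specs <- ramp_specs()
  onset <- 0.5
  trials <- vector("list", n)
  names(trials) <- manifest$trial_id
  manifest$onset_s <- onset

  for (i in seq_len(n)) {
    row <- manifest[i, ]
    meta <- list(participant_id = participant_id, mass_kg = plant$mass_kg,
                 condition_label = row$condition_label,
                 direction_deg = row$direction_deg,
                 magnitude_label = row$magnitude_label,
                 plane = row$plane, start_sign = row$start_sign,
                 onset_s = onset, rep_index = row$rep_index)
    if (row$condition_label == "ramp") {
      prof <- make_ramp_profile(specs[[row$magnitude_label]], dt = dt, hold_s = 0.5)
      platform <- embed_ramp(prof, row$direction_deg, onset, total_s = 2.0, dt = dt)
      trials[[i]] <- simulate_trial(platform, plant, dt = dt, meta = meta,
                                    context = "ramp", seed = trial_seeds[i])
    } else {
      sup <- NULL
      if (row$condition_label == "sinusoid_perturbed") {
        classes <- if (row$rep_index %% 2 == 1) c("accelerating", "braking", "accelerating")
                   else c("braking", "accelerating", "braking")
        sup <- data.frame(crossing = c(5, 9, 13),
                          label = row$magnitude_label,
                          class = classes, stringsAsFactors = FALSE)
      }
      spec <- sinusoid_spec(plane = row$plane, start_sign = row$start_sign,
                            superimposed = sup)
      meta$frequency_hz <- spec$frequency_hz
      prof <- make_sinusoid_profile(spec, dt = dt, tail_s = 1.25)
      platform <- embed_axis(prof, plane_axis(row$plane), onset, dt = dt)
      if (nrow(prof$injections) > 0) {
        ax <- plane_axis(row$plane)
        base_dir <- if (ax == "x") 0 else 90
        meta$superimposed <- data.frame(
          onset_s = prof$injections$onset_s + onset,
          direction_deg = ifelse(prof$injections$sign > 0, base_dir,
                                 (base_dir + 180) %% 360),
          magnitude_label = prof$injections$label,
          class = prof$injections$class, stringsAsFactors = FALSE
        )
      }
      trials[[i]] <- simulate_trial(platform, plant, dt = dt, meta = meta,
                                    context = "sinusoid", seed = trial_seeds[i])
    }
  }
  structure(list(trials = trials, manifest = manifest, plant = plant, seed = seed),
            class = "com_study")
}

#' @export
print.com_study <- function(x, ...) {
  tab <- table(x$manifest$condition_label)
  cat(sprintf("<com_study> %d trials (%s), seed %d\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), x$seed))
  invisible(x)
}

# place a ramp profile (scalar along its heading) into full-length per-axis
# platform channels with a quiet lead-in and tail
embed_ramp <- function(prof, direction_deg, onset_s, total_s, dt) {
  n <- as.integer(round(total_s / dt)) + 1L
  i0 <- as.integer(round(onset_s / dt)) + 1L
  len <- min(length(prof$pos$values), n - i0 + 1L)
  ux <- cospi(direction_deg / 180)
  uy <- sinpi(direction_deg / 180)
  out <- list()
  for (axis in c("x", "y")) {
    u <- if (axis == "x") ux else uy
    for (comp in c("pos", "vel", "acc")) {
      v <- numeric(n)
      if (abs(u) > 1e-12) {
        v[i0:(i0 + len - 1L)] <- u * prof[[comp]]$values[seq_len(len)]
        if (comp == "pos" && i0 + len - 1L < n) {
          v[(i0 + len):n] <- u * prof$pos$values[len]
        }
      }
      out[[paste0(comp, "_", axis)]] <- v
    }
  }
  out
}

# place a single-axis profile into full-length per-axis platform channels
embed_axis <- function(prof, axis, onset_s, dt) {
  n_prof <- length(prof$pos$values)
  i0 <- as.integer(round(onset_s / dt)) + 1L
  n <- n_prof + i0 - 1L
  out <- list()
  for (ax in c("x", "y")) {
    for (comp in c("pos", "vel", "acc")) {
      v <- numeric(n)
      if (ax == axis) v[i0:n] <- prof[[comp]]$values
      out[[paste0(comp, "_", ax)]] <- v
    }
  }
  out
}

#' Write / read a study as a trial directory
#'
#' Writes each trial as wide CSV + JSON sidecar (see [write_trial()]),
#' `manifest.csv`, and `ground_truth.json` holding the plant's ground-truth
#' models (for parameter-recovery checks only).
#'
#' @param study A `com_study`.
#' @param dir Output directory (created if needed).
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   `com_study` (without plant parameters; ground truth is not reloaded).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "com_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$trials)) {
    write_trial(study$trials[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- lapply(study$plant$models, function(set) {
    lapply(set, function(m) jsonlite::fromJSON(jsonlite::toJSON(
      list(joint_id = m$joint_id, axis = m$axis,
           accel_loop = unclass(m$accel_loop),
           residual_loops = lapply(m$residual_loops, unclass)),
      auto_unbox = TRUE, digits = NA), simplifyVector = FALSE))
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  trials <- lapply(manifest$trial_id, function(id) {
    read_trial(file.path(dir, paste0(id, ".csv")))
  })
  names(trials) <- manifest$trial_id
  structure(list(trials = trials, manifest = manifest, plant = NULL, seed = NA),
            class = "com_study")
}
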