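# End-to-end pipeline: simulate -> preprocess/fit -> generalize -> report,
# driven by a single validated configuration object that round-trips through
# JSON, with a reproducibility manifest alongside the outputs.

#' Study configuration
#'
#' Collects every tunable of the pipeline in one validated object: the
#' protocol (directions, magnitudes, repetitions), the plant, the fitting
#' configuration, thresholds, and the seed. All protocol constants default
#' to the study conditions (8 directions x 4 magnitudes x 5 ramp reps, 6
#' sinusoid conditions x 6 reps, 10 Nm exclusion, good fit at R^2 > 0.7 and
#' RMSE < 0.2 Nm/kg, stage-1 stop at 0.95).
#'
#' @param plant A [plant_params()].
#' @param fit A [fit_config()].
#' @param directions_deg,magnitudes,ramp_reps,sinusoid_reps,sinusoid_contexts
#'   Protocol extent (see [study_manifest()]).
#' @param n_participants Number of synthetic participants.
#' @param exclude_threshold_nm Low-torque exclusion threshold (Nm).
#' @param r2_good,rmse_good Good-fit thresholds.
#' @param seed Integer master seed.
#'
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(plant = plant_params(), fit = fit_config(),
                         directions_deg = seq(0, 315, by = 45),
                         magnitudes = names(ramp_specs()),
                         ramp_reps = 5, sinusoid_reps = 6,
                         sinusoid_contexts = c("none", "slow", "fast"),
                         n_participants = 1,
                         exclude_threshold_nm = 10,
                         r2_good = 0.7, rmse_good = 0.2,
                         seed = 1L) {
  stopifnot(inherits(plant, "plant_params"), inherits(fit, "fit_config"))
  if (ramp_reps < 1 || sinusoid_reps < 1) {
    stop("repetition counts must be at least 1", call. = FALSE)
  }
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (!all(magnitudes %in% names(ramp_specs()))) {
    stop("unknown magnitude label", call. = FALSE)
  }
  if (!all(directions_deg %% 45 == 0)) {
    stop("directions must be multiples of 45 deg", call. = FALSE)
  }
  structure(
    list(plant = plant, fit = fit, directions_deg = directions_deg,
         magnitudes = magnitudes, ramp_reps = ramp_reps,
         sinusoid_reps = sinusoid_reps, sinusoid_contexts = sinusoid_contexts,
         n_participants = n_participants,
         exclude_threshold_nm = exclude_threshold_nm,
         r2_good = r2_good, rmse_good = rmse_good, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Write / read a study configuration as JSON
#'
#' The on-disk representation is lossless: reading back a written
#' configuration reproduces the object, including the plant's ground-truth
#' models. Validation happens in the constructors on load.
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` the restored `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  obj <- unclass(config)
  obj$fit <- unclass(config$fit)
  p <- unclass(config$plant)
  p$models <- lapply(p$models, function(set) {
    lapply(set, function(m) {
      list(joint_id = m$joint_id, axis = m$axis,
           accel_loop = unclass(m$accel_loop),
           residual_loops = lapply(m$residual_loops, unclass),
           train_condition = m$train_condition)
    })
  })
  obj$plant <- p
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  mk_loop <- function(l) feedback_loop(l$k_d, l$k_v, l$k_a, l$lambda_s,
                                       com_sign = l$com_sign,
                                       torque_sign = l$torque_sign)
  models <- lapply(obj$plant$models, function(set) {
    lapply(set, function(m) {
      com_feedback_model(joint_id = m$joint_id, axis = m$axis,
                         accel_loop = mk_loop(m$accel_loop),
                         residual_loops = lapply(m$residual_loops, mk_loop),
                         train_condition = m$train_condition)
    })
  })
  plant <- plant_params(mass_kg = obj$plant$mass_kg,
                        com_height_m = obj$plant$com_height_m,
                        damping_ratio = obj$plant$damping_ratio,
                        noise_frac = obj$plant$noise_frac,
                        context_dissociation = obj$plant$context_dissociation,
                        models = models)
  fit <- fit_config(lambda_bounds_accel = unlist(obj$fit$lambda_bounds_accel),
                    lambda_bounds_residual = unlist(obj$fit$lambda_bounds_residual),
                    lambda_grid_step = obj$fit$lambda_grid_step,
                    lambda_refine_step = obj$fit$lambda_refine_step,
                    gain_scale_mult = obj$fit$gain_scale_mult,
                    stage1_r2_stop = obj$fit$stage1_r2_stop,
                    fit_window = unlist(obj$fit$fit_window),
                    background_window_s = obj$fit$background_window_s,
                    multistart_count = obj$fit$multistart_count,
                    refit_accel = obj$fit$refit_accel,
                    max_sweeps = obj$fit$max_sweeps,
                    seed = obj$fit$seed)
  study_config(plant = plant, fit = fit,
               directions_deg = unlist(obj$directions_deg),
               magnitudes = unlist(obj$magnitudes),
               ramp_reps = obj$ramp_reps, sinusoid_reps = obj$sinusoid_reps,
               sinusoid_contexts = unlist(obj$sinusoid_contexts),
               n_participants = obj$n_participants,
               exclude_threshold_nm = obj$exclude_threshold_nm,
               r2_good = obj$r2_good, rmse_good = obj$rmse_good,
               seed = obj$seed)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured study for each synthetic participant, fits the
#' cardinal ramp models, runs all four generalization protocols, and writes
#' the result tables (`results.csv`, `report.csv`, `report.txt`), a
#' parameter-count summary (`parameter_counts.csv`), representative-trace
#' plots (`traces.pdf`) and a reproducibility manifest (`manifest.json`)
#' into `out_dir`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param protocols Subset of `c("direction", "magnitude", "sinusoid",
#'   "superimposed_slow", "superimposed_fast")` to run.
#' @param quiet Suppress progress messages.
#'
#' @return Invisibly, a list with `results` (per-cell data frame over all
#'   participants), `report` (aggregate table), `parameter_counts` and
#'   `fits` (per participant).
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         protocols = c("direction", "magnitude", "sinusoid",
                                       "superimposed_slow", "superimposed_fast"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  protocols <- match.arg(protocols, several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  all_results <- list()
  param_rows <- list()
  fits_by_pid <- list()
  first_study <- NULL

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("S%02d", p)
    p_seed <- config$seed + 1000L * (p - 1L)
    say("[%s] simulating study (seed %d)", pid, p_seed)
    study <- generate_study(config$plant, seed = p_seed, participant_id = pid,
                            directions_deg = config$directions_deg,
                            magnitudes = config$magnitudes,
                            ramp_reps = config$ramp_reps,
                            sinusoid_reps = config$sinusoid_reps,
                            sinusoid_contexts = config$sinusoid_contexts)
    if (is.null(first_study)) first_study <- study
    say("[%s] fitting cardinal ramp models", pid)
    fits <- fit_ramp_models(study, config$fit,
                            magnitudes = config$magnitudes,
                            exclude_threshold_nm = config$exclude_threshold_nm)
    fits_by_pid[[pid]] <- fits
    for (mag in names(fits)) {
      for (dir in names(fits[[mag]])) {
        for (joint in names(fits[[mag]][[dir]])) {
          fr <- fits[[mag]][[dir]][[joint]]
          param_rows[[length(param_rows) + 1L]] <- data.frame(
            participant_id = pid, magnitude = mag,
            direction_deg = as.numeric(dir), joint = joint,
            active_parameters = fr$active_parameters,
            stopped_after_stage1 = fr$stopped_after_stage1,
            r2_train = fr$r2_train, stringsAsFactors = FALSE)
        }
      }
    }
    for (proto in protocols) {
      say("[%s] protocol: %s", pid, proto)
      res <- switch(proto,
        direction = run_direction_generalization(
          study, config$fit, exclude_threshold_nm = config$exclude_threshold_nm,
          fits = fits),
        magnitude = run_magnitude_generalization(
          study, config$fit, exclude_threshold_nm = config$exclude_threshold_nm,
          fits = fits),
        run_context_generalization(
          study, config$fit, context = proto,
          exclude_threshold_nm = config$exclude_threshold_nm, fits = fits)
      )
      if (!is.null(res)) all_results[[length(all_results) + 1L]] <- res
    }
  }

  results <- do.call(rbind, all_results)
  report <- aggregate_report(results, config$r2_good, config$rmse_good)
  parameter_counts <- do.call(rbind, param_rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    writeLines(utils::capture.output(format_report(report)),
               file.path(out_dir, "report.txt"))
    utils::write.csv(parameter_counts, file.path(out_dir, "parameter_counts.csv"),
                     row.names = FALSE)
    plot_representative_traces(first_study, fits_by_pid[[1L]],
                               file.path(out_dir, "traces.pdf"))
    manifest <- list(package_version = as.character(utils::packageVersion("comfeedback")),
                     r_version = R.version.string,
                     seed = config$seed,
                     n_participants = config$n_participants,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    write_study_config(config, file.path(out_dir, "config.json"))
  }
  invisible(list(results = results, report = report,
                 parameter_counts = parameter_counts, fits = fits_by_pid))
}

# representative measured-vs-predicted traces for the first fitted cells
plot_representative_traces <- function(study, fits, path) {
  grDevices::pdf(path, width = 8, height = 10)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(4, 1), mar = c(4, 4, 2, 1))
  mag <- names(fits)[[1L]]
  for (joint in JOINTS) {
    fr <- NULL
    for (dir in names(fits[[mag]])) {
      fr <- fits[[mag]][[dir]][[joint]]
      if (!is.null(fr)) break
    }
    if (is.null(fr)) next
    dir <- fr$model$train_condition$direction_deg
    avg <- ramp_average(study, dir, mag)
    tau <- avg_torque(avg, joint)
    com <- com_state_from_trial(avg$trial, fr$model$axis)
    pred <- predict_torque(fr$model, com)
    graphics::plot(ts_time(tau), tau$values, type = "l", col = "grey40",
                   xlab = "time re onset (s)", ylab = "torque (Nm)",
                   main = sprintf("%s, %s at %g deg (train R2 = %.3f)",
                                  joint, mag, dir, fr$r2_train))
    graphics::lines(ts_time(pred), pred$values, col = "black", lty = 2)
    graphics::abline(v = 0, lty = 3)
    graphics::legend("topright", c("simulated", "model"), lty = c(1, 2),
                     col = c("grey40", "black"), bty = "n")
  }
}
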