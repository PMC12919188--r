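# Multichannel trial container: named time_series channels on a shared time
# base plus trial metadata, with windowing and a plain-text on-disk layout
# (wide CSV + JSON metadata sidecar).

#' Create a multichannel trial
#'
#' Bundles named [time_series()] channels that share a time base with trial
#' metadata. Metadata fields used by the pipeline are `participant_id`,
#' `mass_kg`, `condition_label` (`"ramp"`, `"sinusoid"` or
#' `"sinusoid_perturbed"`), `direction_deg`, `magnitude_label`, `plane`,
#' `start_sign`, `onset_s` (perturbation or platform-motion onset) and
#' `rep_index`. Sinusoid trials with superimposed perturbations additionally
#' carry `meta$superimposed`, a data frame with one row per injected
#' perturbation (`onset_s`, `direction_deg`, `magnitude_label`, `class`).
#'
#' @param channels Named list of `time_series` sharing `t0`, `dt` and length.
#' @param meta Named list of trial metadata; must include positive `mass_kg`
#'   and an `onset_s` inside the recorded interval.
#'
#' @return An object of class `"ts_trial"`.
#' @export
ts_trial <- function(channels, meta) {
  if (length(channels) == 0L || is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list", call. = FALSE)
  }
  ok <- vapply(channels, inherits, logical(1), what = "time_series")
  if (!all(ok)) stop("all channels must be time_series objects", call. = FALSE)
  ref <- channels[[1L]]
  same <- vapply(channels, function(ch) {
    isTRUE(all.equal(ch$t0, ref$t0)) && isTRUE(all.equal(ch$dt, ref$dt)) &&
      length(ch$values) == length(ref$values)
  }, logical(1))
  if (!all(same)) stop("all channels must share t0, dt and length", call. = FALSE)
  if (is.null(meta$mass_kg) || !is.finite(meta$mass_kg) || meta$mass_kg <= 0) {
    stop("`meta$mass_kg` must be a positive number", call. = FALSE)
  }
  if (is.null(meta$onset_s)) stop("`meta$onset_s` is required", call. = FALSE)
  if (meta$onset_s < ref$t0 - ref$dt / 2 || meta$onset_s > ts_end(ref) + ref$dt / 2) {
    stop("`meta$onset_s` lies outside the recorded interval", call. = FALSE)
  }
  structure(list(channels = channels, meta = meta), class = "ts_trial")
}

#' @export
print.ts_trial <- function(x, ...) {
  ref <- x$channels[[1L]]
  cat(sprintf(
    "<ts_trial> %s | %d channels x %d samples @ %.6g Hz, onset %.3f s\n",
    trial_key(x), length(x$channels), length(ref$values), 1 / ref$dt, x$meta$onset_s
  ))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# internal: short condition key for messages and grouping
trial_key <- function(trial) {
  m <- trial$meta
  paste(
    m$condition_label %||% "?",
    if (!is.null(m$direction_deg)) paste0(m$direction_deg, "deg") else m$plane %||% "",
    m$magnitude_label %||% "",
    sep = " "
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a channel from a trial
#'
#' @param trial A `ts_trial`.
#' @param name Channel name.
#' @return The channel as a `time_series`.
#' @export
trial_channel <- function(trial, name) {
  stopifnot(inherits(trial, "ts_trial"))
  ch <- trial$channels[[name]]
  if (is.null(ch)) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(trial$channels), collapse = ", ")), call. = FALSE)
  }
  ch
}

#' Truncate a trial to a window around the perturbation onset
#'
#' Cuts every channel to the closed interval
#' `[onset - pre_s, onset + post_s]` (inclusive endpoints, so a window of
#' `pre_s = 0.25`, `post_s = 1` at 1 kHz yields 1251 samples) and re-bases
#' time so the onset sits at `t = 0`; `meta$onset_s` becomes 0 and
#' superimposed-perturbation onsets, if present, are shifted accordingly.
#'
#' @param trial A `ts_trial`.
#' @param pre_s Seconds retained before the onset (>= 0).
#' @param post_s Seconds retained after the onset (>= 0).
#' @param onset_s Onset time to cut around; defaults to `meta$onset_s`.
#'
#' @return The truncated, re-based `ts_trial`.
#' @export
truncate_window <- function(trial, pre_s, post_s, onset_s = NULL) {
  stopifnot(inherits(trial, "ts_trial"))
  if (pre_s < 0 || post_s < 0) stop("window extents must be >= 0", call. = FALSE)
  onset <- onset_s %||% trial$meta$onset_s
  ref <- trial$channels[[1L]]
  i_on <- as.integer(round((onset - ref$t0) / ref$dt)) + 1L
  n_pre <- as.integer(round(pre_s / ref$dt))
  n_post <- as.integer(round(post_s / ref$dt))
  i0 <- i_on - n_pre
  i1 <- i_on + n_post
  if (i0 < 1L || i1 > length(ref$values)) {
    stop("window exceeds the recorded interval", call. = FALSE)
  }
  new_t0 <- -n_pre * ref$dt
  channels <- lapply(trial$channels, function(ch) {
    time_series(ch$values[i0:i1], dt = ch$dt, t0 = new_t0, units = ch$units)
  })
  meta <- trial$meta
  shift <- onset
  meta$onset_s <- 0
  if (!is.null(meta$superimposed)) {
    meta$superimposed$onset_s <- meta$superimposed$onset_s - shift
  }
  ts_trial(channels, meta)
}

#' Write / read a trial as wide CSV plus JSON metadata sidecar
#'
#' The on-disk layout is one wide CSV per trial (`time_s` column plus one
#' column per channel, e.g. `com_d_x_m`, `com_v_x_mps`, `com_a_x_mps2`,
#' `tau_ankle_pf_Nm`) and a `.json` sidecar with the metadata. Channel units
#' are carried in a `units` map inside the sidecar.
#'
#' @param trial A `ts_trial`.
#' @param path Path of the CSV file; the sidecar replaces the extension with
#'   `.json`.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   the reconstructed `ts_trial`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "ts_trial"))
  ref <- trial$channels[[1L]]
  df <- data.frame(time_s = ts_time(ref))
  for (nm in names(trial$channels)) df[[nm]] <- trial$channels[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  meta <- trial$meta
  meta$.units <- lapply(trial$channels, function(ch) ch$units)
  meta$.dt <- ref$dt
  meta$.t0 <- ref$t0
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  units <- meta$.units
  dt <- meta$.dt
  t0 <- meta$.t0
  meta$.units <- NULL
  meta$.dt <- NULL
  meta$.t0 <- NULL
  if (!is.null(meta$superimposed)) meta$superimposed <- as.data.frame(meta$superimposed)
  ch_names <- setdiff(names(df), "time_s")
  channels <- lapply(ch_names, function(nm) {
    time_series(df[[nm]], dt = dt, t0 = t0, units = units[[nm]] %||% "")
  })
  names(channels) <- ch_names
  ts_trial(channels, meta)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
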