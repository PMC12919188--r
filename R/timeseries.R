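# Uniformly sampled signal container and the primitive operations every other
# module is built on: zero-phase low-pass filtering, linear resampling,
# sample-quantized delays, half-wave rectification and window truncation.

#' Create a uniformly sampled time series
#'
#' The basic signal container used throughout the package: a start time, a
#' fixed sample interval, and a vector of finite sample values with a
#' free-text unit label.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param dt Sample interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Free-text unit label carried along with the signal.
#'
#' @return An object of class `"time_series"`.
#' @export
#' @examples
#' x <- time_series(sin(seq(0, 1, by = 0.01)), dt = 0.01, units = "m")
#' x
time_series <- function(values, dt, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (length(values) < 1L) stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values))) stop("all samples must be finite", call. = FALSE)
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values, units = as.character(units)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %d samples @ %.6g Hz, t = [%.4g, %.4g] s%s\n",
    length(x$values), 1 / x$dt, x$t0, ts_end(x),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x A `time_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @rdname ts_time
#' @export
ts_end <- function(x) x$t0 + (length(x$values) - 1) * x$dt

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = ts_time(x), value = x$values)
}

# internal: new time_series reusing time base/units of `x`
ts_like <- function(x, values, units = x$units) {
  time_series(values, dt = x$dt, t0 = x$t0, units = units)
}

# internal: index of the sample nearest to time t (1-based)
ts_index <- function(x, t) {
  i <- as.integer(round((t - x$t0) / x$dt)) + 1L
  if (any(i < 1L | i > length(x$values))) {
    stop("time outside the recorded interval", call. = FALSE)
  }
  i
}

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' ([signal::filtfilt()]) so the result has zero phase lag. The filter is
#' designed at half the nominal order so that the combined forward-backward
#' pass has the stated order; e.g. `order = 4` applies a second-order
#' Butterworth twice, matching the common motion-capture convention of a
#' "fourth-order zero-phase" filter. Phase distortion would bias fitted
#' feedback delays, which is why only the zero-phase form is offered.
#'
#' @param x A `time_series` with at least 2 samples.
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly below the
#'   Nyquist frequency `0.5 / dt`.
#' @param order Nominal (combined) filter order; a positive even integer.
#'
#' @return A filtered `time_series` on the same time base.
#' @export
#' @examples
#' x <- time_series(sin(2 * pi * 1 * seq(0, 2, by = 0.001)), dt = 0.001)
#' y <- lowpass_filter(x, cutoff_hz = 10, order = 4)
lowpass_filter <- function(x, cutoff_hz, order = 4) {
  stopifnot(inherits(x, "time_series"))
  if (length(x$values) < 2L) stop("need at least 2 samples to filter", call. = FALSE)
  nyq <- 0.5 / x$dt
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop(sprintf("`cutoff_hz` must lie in (0, %g) for dt = %g", nyq, x$dt), call. = FALSE)
  }
  if (order %% 2 != 0 || order < 2) stop("`order` must be a positive even integer", call. = FALSE)
  bf <- signal::butter(order / 2, cutoff_hz / nyq, type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (the padding is stripped from the result)
  v <- x$values
  n <- length(v)
  pad <- min(n - 1L, max(10L, as.integer(ceiling(3 / (cutoff_hz * x$dt)))))
  head_pad <- 2 * v[1L] - v[seq(pad + 1L, 2L)]
  tail_pad <- 2 * v[n] - v[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
  ts_like(x, y[(pad + 1L):(pad + n)])
}

#' Resample a time series by linear interpolation
#'
#' Samples the signal on a new uniform grid at `target_hz`, starting at the
#' original `t0` and extending to the last original sample time (endpoints
#' preserved). Values between original samples are linearly interpolated.
#'
#' @param x A `time_series` with at least 2 samples.
#' @param target_hz Target sampling rate in Hz (> 0).
#'
#' @return A `time_series` at the new rate.
#' @export
resample_linear <- function(x, target_hz) {
  stopifnot(inherits(x, "time_series"))
  if (length(x$values) < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  if (!is.finite(target_hz) || target_hz <= 0) {
    stop("`target_hz` must be positive", call. = FALSE)
  }
  new_dt <- 1 / target_hz
  t_new <- seq(x$t0, ts_end(x), by = new_dt)
  if (length(t_new) == 0L) stop("target grid is empty", call. = FALSE)
  v <- stats::approx(ts_time(x), x$values, xout = t_new, method = "linear")$y
  time_series(v, dt = new_dt, t0 = x$t0, units = x$units)
}

#' Delay a signal by a fixed lag
#'
#' Returns `y(t) = x(t - lambda_s)` with the lag rounded to the nearest whole
#' number of samples. The leading gap is back-filled with the signal's first
#' value, consistent with a quiescent pre-perturbation background. Output has
#' the same length and time base as the input.
#'
#' @param x A `time_series`.
#' @param lambda_s Delay in seconds (>= 0); must be shorter than the record.
#'
#' @return The delayed `time_series`.
#' @export
delay_signal <- function(x, lambda_s) {
  stopifnot(inherits(x, "time_series"))
  if (!is.finite(lambda_s) || lambda_s < 0) stop("`lambda_s` must be >= 0", call. = FALSE)
  n <- as.integer(round(lambda_s / x$dt))
  len <- length(x$values)
  if (n >= len) stop("delay longer than the record", call. = FALSE)
  if (n == 0L) return(x)
  ts_like(x, c(rep(x$values[1L], n), x$values[seq_len(len - n)]))
}

#' Split a signal into half-wave rectified components
#'
#' Decomposes a signal into its positive part `max(x, 0)` and negative part
#' `min(x, 0)`. The two components sum to the original signal exactly.
#'
#' @param x A `time_series`.
#' @return A list with `time_series` elements `pos` and `neg`.
#' @export
halfwave_split <- function(x) {
  stopifnot(inherits(x, "time_series"))
  list(
    pos = ts_like(x, pmax(x$values, 0)),
    neg = ts_like(x, pmin(x$values, 0))
  )
}

# internal: half-wave component selected by a gating label
halfwave_select <- function(values, com_sign) {
  switch(com_sign,
    "+"    = pmax(values, 0),
    "-"    = pmin(values, 0),
    "both" = values,
    stop("invalid `com_sign`: ", com_sign, call. = FALSE)
  )
}
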