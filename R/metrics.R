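# Fit-quality metrics: coefficient of determination and body-mass-normalized
# root-mean-square error, plus the background-torque reference removal.

#' Coefficient of determination between a torque trace and its prediction
#'
#' `R^2 = 1 - sum((tau - tau_hat)^2) / sum((tau - mean(tau))^2)`. Can be
#' negative when a prediction is worse than the target mean (possible on
#' transfer/test data). A zero-variance target is unusable and raises an
#' error.
#'
#' @param tau Measured torque, a `time_series` or numeric vector.
#' @param tau_hat Predicted torque of the same length.
#' @return R-squared as a plain number.
#' @export
compute_r2 <- function(tau, tau_hat) {
  y <- if (inherits(tau, "time_series")) tau$values else as.numeric(tau)
  yh <- if (inherits(tau_hat, "time_series")) tau_hat$values else as.numeric(tau_hat)
  if (length(y) != length(yh)) stop("traces must have equal length", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance target: trial unusable for R^2", call. = FALSE)
  1 - sum((y - yh)^2) / ss_tot
}

#' Body-mass-normalized RMSE between a torque trace and its prediction
#'
#' `sqrt(mean((tau - tau_hat)^2)) / mass_kg`, in Nm/kg, so errors are
#' comparable across participants of different size.
#'
#' @inheritParams compute_r2
#' @param mass_kg Participant mass in kg (> 0).
#' @return RMSE per kilogram (Nm/kg).
#' @export
compute_rmse_per_kg <- function(tau, tau_hat, mass_kg) {
  if (!is.finite(mass_kg) || mass_kg <= 0) stop("`mass_kg` must be positive", call. = FALSE)
  y <- if (inherits(tau, "time_series")) tau$values else as.numeric(tau)
  yh <- if (inherits(tau_hat, "time_series")) tau_hat$values else as.numeric(tau_hat)
  if (length(y) != length(yh)) stop("traces must have equal length", call. = FALSE)
  sqrt(mean((y - yh)^2)) / mass_kg
}

#' Remove the pre-perturbation background torque
#'
#' Computes the mean torque over the window `[onset - background_window_s,
#' onset)` and subtracts it from the whole trace, so the model is fit to the
#' perturbation-evoked deviation from quiet stance.
#'
#' @param tau Torque `time_series`.
#' @param onset_s Perturbation onset time (s) on the trace's time base.
#' @param background_window_s Length of the pre-onset averaging window (s).
#' @return A list with `trace` (background-subtracted `time_series`) and
#'   `background` (the subtracted mean, Nm).
#' @export
remove_background_torque <- function(tau, onset_s, background_window_s = 0.25) {
  stopifnot(inherits(tau, "time_series"))
  if (background_window_s <= 0) stop("`background_window_s` must be > 0", call. = FALSE)
  t <- ts_time(tau)
  sel <- t >= onset_s - background_window_s - tau$dt / 2 & t < onset_s - tau$dt / 2
  if (!any(sel)) stop("background window contains no samples", call. = FALSE)
  bg <- mean(tau$values[sel])
  list(trace = ts_like(tau, tau$values - bg), background = bg)
}
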