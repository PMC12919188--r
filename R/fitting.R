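# Staged, bounded identification of a delayed CoM feedback model from one
# averaged, background-subtracted torque trace.
#
# Stage 1 fits the instantaneous acceleration loop alone (grid search on its
# delay, closed-form gain). If it explains more than the stage-1 stopping
# fraction of the torque variance the procedure ends there; otherwise the
# four sign-gated residual loops are fit with a seeded multistart coordinate
# descent over the residual delay grid, solving the convex bounded
# least-squares gain problem at every delay candidate.

#' Fitting configuration
#'
#' @param lambda_bounds_accel Delay bounds (s) for the instantaneous
#'   acceleration loop. Default `c(0, 0.020)`: the acceleration response is
#'   attributed to intrinsic limb mechanics, so its latency is near zero.
#' @param lambda_bounds_residual Delay bounds (s) for the residual loops.
#'   Default `c(0.040, 0.250)` spans physiological sensorimotor feedback
#'   latencies (reactive responses begin roughly 50 ms after perturbation).
#' @param lambda_grid_step Delay grid step (s) for the coarse search.
#' @param lambda_refine_step Step (s) of the local refinement around the best
#'   grid point (delays are always quantized to whole samples).
#' @param gain_scale_mult Gain magnitude caps are this multiple of a scale
#'   estimate `diff(range(tau)) / diff(range(channel))` per kinematic channel.
#' @param stage1_r2_stop Stage-1 stopping fraction; fitting ends after the
#'   acceleration loop if it explains strictly more than this fraction of the
#'   torque variance.
#' @param fit_window Optimization window (s) relative to perturbation onset.
#' @param background_window_s Pre-onset window (s) used for background torque.
#' @param multistart_count Number of coordinate-descent starts for the
#'   residual delay search (first start is deterministic, the rest seeded).
#' @param refit_accel If `TRUE` (default) the acceleration gain and delay are
#'   re-estimated jointly with the residual loops during stage 2; if `FALSE`
#'   the stage-1 acceleration loop is frozen and stage 2 fits the residual.
#' @param prune_tol Parsimony tolerance of the backward-elimination pass: a
#'   gain is retained only if removing it worsens the residual SSE by more
#'   than this fraction. Keeps the active-parameter count honest by
#'   discarding terms whose contribution is indistinguishable from the
#'   residual noise floor.
#' @param max_sweeps Maximum coordinate-descent sweeps over the loops.
#' @param seed Integer seed making the multistart (and hence the whole fit)
#'   deterministic.
#'
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(lambda_bounds_accel = c(0, 0.020),
                       lambda_bounds_residual = c(0.040, 0.250),
                       lambda_grid_step = 0.005,
                       lambda_refine_step = 0.001,
                       gain_scale_mult = 10,
                       stage1_r2_stop = 0.95,
                       fit_window = c(0, 1.0),
                       background_window_s = 0.25,
                       multistart_count = 3,
                       refit_accel = TRUE,
                       prune_tol = 0.05,
                       max_sweeps = 6,
                       seed = 1L) {
  chk_bounds <- function(b, nm) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] < 0 || b[1] >= b[2]) {
      stop(sprintf("`%s` must be 0 <= lo < hi", nm), call. = FALSE)
    }
  }
  chk_bounds(lambda_bounds_accel, "lambda_bounds_accel")
  chk_bounds(lambda_bounds_residual, "lambda_bounds_residual")
  if (stage1_r2_stop <= 0 || stage1_r2_stop >= 1) {
    stop("`stage1_r2_stop` must lie in (0, 1)", call. = FALSE)
  }
  if (lambda_grid_step <= 0 || lambda_refine_step <= 0) {
    stop("grid steps must be positive", call. = FALSE)
  }
  if (multistart_count < 1) stop("`multistart_count` must be >= 1", call. = FALSE)
  if (prune_tol < 0) stop("`prune_tol` must be >= 0", call. = FALSE)
  structure(
    list(lambda_bounds_accel = lambda_bounds_accel,
         lambda_bounds_residual = lambda_bounds_residual,
         lambda_grid_step = lambda_grid_step,
         lambda_refine_step = lambda_refine_step,
         gain_scale_mult = gain_scale_mult,
         stage1_r2_stop = stage1_r2_stop,
         fit_window = fit_window,
         background_window_s = background_window_s,
         multistart_count = multistart_count,
         refit_accel = refit_accel,
         prune_tol = prune_tol,
         max_sweeps = max_sweeps,
         seed = as.integer(seed)),
    class = "fit_config"
  )
}

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# lag a vector by `lag` samples, back-filling with its first value
shift_fill <- function(v, lag) {
  if (lag == 0L) return(v)
  n <- length(v)
  if (lag >= n) stop("delay longer than the record", call. = FALSE)
  c(rep(v[1L], lag), v[seq_len(n - lag)])
}

# rectified kinematic channels, computed once per fit
rectified_channels <- function(com) {
  out <- list()
  for (ch in c("d", "v", "a")) {
    v <- com[[ch]]$values
    out[[ch]] <- list("+" = pmax(v, 0), "-" = pmin(v, 0), both = v)
  }
  out
}

# sign interval for one gain from the loop gating: a loop reconstructing
# positive torque from a positive-rectified input needs nonnegative gains;
# crossed signs need nonpositive gains; unconstrained otherwise
gain_sign <- function(com_sign, torque_sign) {
  cs <- switch(com_sign, "+" = 1, "-" = -1, both = 0)
  ts <- switch(torque_sign, "+" = 1, "-" = -1, none = 0)
  cs * ts
}

# bounded least squares min ||X g - y||^2 s.t. lo <= g <= hi, by an
# active-set method: solve the free subset unconstrained, clamp violators to
# their nearest bound, and release clamped variables whose KKT multiplier has
# the wrong sign. The problem is a small convex box-constrained QP, so this
# terminates at the global optimum. Degenerate (near-zero) columns get gain 0
# with a warning.
bounded_lsq <- function(X, y, lo, hi, warn = TRUE) {
  p <- ncol(X)
  g <- numeric(p)
  norms <- sqrt(colSums(X^2))
  scale <- max(norms, sqrt(sum(y^2)), 1e-12)
  keep <- norms > 1e-10 * scale
  if (!all(keep) && warn) {
    warning("rank-deficient regressors: degenerate columns fixed at 0", call. = FALSE)
  }
  if (!any(keep)) return(g)
  Xk <- X[, keep, drop = FALSE]
  lok <- lo[keep]; hik <- hi[keep]
  pk <- ncol(Xk)
  span <- pmax(abs(lok), abs(hik), 1)
  tol <- 1e-9 * span
  gk <- pmin(pmax(numeric(pk), lok), hik)
  free <- lok < hik
  gtol <- 1e-8 * scale^2

  ls_free <- function(fr, fixed_part) {
    f <- stats::.lm.fit(Xk[, fr, drop = FALSE], y - fixed_part)
    co <- numeric(sum(fr))
    co[f$pivot] <- f$coefficients
    co[is.na(co)] <- 0
    co
  }

  for (it in seq_len(10L * pk + 10L)) {
    if (any(free)) {
      fixed_part <- if (all(free)) numeric(length(y)) else {
        drop(Xk[, !free, drop = FALSE] %*% gk[!free])
      }
      cand <- ls_free(free, fixed_part)
      viol_lo <- cand < lok[free] - tol[free]
      viol_hi <- cand > hik[free] + tol[free]
      if (any(viol_lo) || any(viol_hi)) {
        # clamp violators to their nearest bound and re-solve
        idx_free <- which(free)
        cand <- pmin(pmax(cand, lok[free]), hik[free])
        gk[idx_free] <- cand
        clamp <- idx_free[viol_lo | viol_hi]
        free[clamp] <- FALSE
        next
      }
      gk[free] <- pmin(pmax(cand, lok[free]), hik[free])
    }
    # KKT check on clamped variables: release those that want to move inward
    w <- drop(crossprod(Xk, drop(Xk %*% gk) - y))   # gradient of 0.5*SSE
    bound_vars <- which(!free & lok < hik)
    if (length(bound_vars) == 0L) break
    at_lo <- bound_vars[abs(gk[bound_vars] - lok[bound_vars]) <= tol[bound_vars]]
    at_hi <- bound_vars[abs(gk[bound_vars] - hik[bound_vars]) <= tol[bound_vars]]
    rel <- c(at_lo[w[at_lo] < -gtol], at_hi[w[at_hi] > gtol])
    if (length(rel) == 0L) break
    # release the single worst violator to avoid cycling
    worst <- rel[which.max(abs(w[rel]))]
    free[worst] <- TRUE
  }
  g[keep] <- gk
  g
}

#' Bound-constrained gain fit at fixed loop delays
#'
#' With all loop delays fixed, the model is linear in the gains: the
#' regressor matrix columns are the delayed, half-wave-rectified CoM
#' channels of each loop, so the inner problem is a convex bounded
#' least-squares problem solved to optimality. Gain sign constraints follow
#' each loop's gating (a loop reconstructing the positive torque component
#' from the positive CoM half-wave gets nonnegative gain bounds, crossed
#' signs nonpositive), with magnitudes capped at `gain_scale_mult` times a
#' per-channel scale estimate.
#'
#' @param com A `com_state` on the trace's time base.
#' @param tau Background-subtracted torque `time_series` on the same base.
#' @param loops List of `feedback_loop`s whose gating and `lambda_s` define
#'   the regressors; their gain values are ignored.
#' @param cfg A [fit_config()].
#' @param fit_window Optimization window (s); defaults to `cfg$fit_window`.
#'
#' @return The list of loops with fitted gains filled in.
#' @export
fit_gains_at_fixed_delays <- function(com, tau, loops, cfg = fit_config(),
                                      fit_window = cfg$fit_window) {
  stopifnot(inherits(com, "com_state"), inherits(tau, "time_series"))
  rect <- rectified_channels(com)
  idx <- fit_indices(tau, fit_window)
  caps <- gain_caps(com, tau, idx, cfg)
  sol <- solve_gains(rect, tau$values, idx, loops,
                     lag_of(loops, tau$dt), caps, tau$dt)
  fill_gains(loops, sol$gains)
}

# indices of the optimization window
fit_indices <- function(tau, fit_window) {
  t <- ts_time(tau)
  idx <- which(t >= fit_window[1] - tau$dt / 2 & t <= fit_window[2] + tau$dt / 2)
  if (length(idx) < 2L) stop("fit window contains fewer than 2 samples", call. = FALSE)
  idx
}

# per-channel gain magnitude caps from a data scale estimate
gain_caps <- function(com, tau, idx, cfg) {
  tau_rng <- diff(range(tau$values[idx]))
  if (tau_rng == 0) tau_rng <- 1
  caps <- numeric(3)
  names(caps) <- c("d", "v", "a")
  for (ch in names(caps)) {
    ch_rng <- diff(range(com[[ch]]$values))
    caps[[ch]] <- if (ch_rng > 0) cfg$gain_scale_mult * tau_rng / ch_rng else 0
  }
  caps
}

lag_of <- function(loops, dt) {
  vapply(loops, function(l) as.integer(round(l$lambda_s / dt)), integer(1))
}

# fast solver context for the delay search: the regressor matrix lives in a
# closure; changing one loop's delay rewrites only that loop's columns, and
# shifted columns are memoised per (loop, lag)
make_gain_solver <- function(rect, target_values, idx, skeletons, caps, warn = FALSE) {
  chans <- c("d", "v", "a")
  n_loops <- length(skeletons)
  cols_of <- vector("list", n_loops)
  chan_of <- character(0)
  lo <- numeric(0); hi <- numeric(0)
  for (i in seq_len(n_loops)) {
    l <- skeletons[[i]]
    use <- if (isTRUE(attr(l, "accel_only"))) "a" else chans
    cols_of[[i]] <- length(chan_of) + seq_along(use)
    chan_of <- c(chan_of, use)
    s <- gain_sign(l$com_sign, l$torque_sign)
    cap <- unname(caps[use])
    lo <- c(lo, if (s > 0) rep(0, length(use)) else -cap)
    hi <- c(hi, if (s < 0) rep(0, length(use)) else cap)
  }
  p <- length(chan_of)
  X <- matrix(0, length(idx), p)
  y <- target_values[idx]
  cache <- lapply(seq_len(n_loops), function(i) new.env(parent = emptyenv()))
  cur <- rep(-1L, n_loops)

  set_lags <- function(lags) {
    for (i in seq_len(n_loops)) {
      if (lags[i] == cur[i]) next
      key <- as.character(lags[i])
      block <- cache[[i]][[key]]
      if (is.null(block)) {
        cs <- skeletons[[i]]$com_sign
        block <- vapply(chan_of[cols_of[[i]]], function(ch) {
          shift_fill(rect[[ch]][[cs]], lags[i])[idx]
        }, numeric(length(idx)))
        assign(key, block, envir = cache[[i]])
      }
      X[, cols_of[[i]]] <<- block
      cur[i] <<- lags[i]
    }
  }

  solve_at <- function(lags) {
    set_lags(lags)
    g <- bounded_lsq(X, y, lo, hi, warn = warn)
    gains <- matrix(0, n_loops, 3, dimnames = list(NULL, chans))
    for (i in seq_len(n_loops)) {
      gains[i, match(chan_of[cols_of[[i]]], chans)] <- g[cols_of[[i]]]
    }
    resid <- y - drop(X %*% g)
    list(gains = gains, sse = sum(resid^2))
  }
  solve_at
}

# core linear solve: build the regressor matrix for the given loops/lags and
# fit bounded gains. Returns the gain matrix (loop x channel) and the SSE.
solve_gains <- function(rect, tau_values, idx, loops, lags, caps, dt, warn = TRUE) {
  chans <- c("d", "v", "a")
  cols <- list()
  lo <- numeric(0)
  hi <- numeric(0)
  map <- list()
  for (i in seq_along(loops)) {
    l <- loops[[i]]
    for (ch in chans) {
      if (inherits(l, "feedback_loop") && l$com_sign == "both" && l$torque_sign == "none" &&
          ch != "a" && isTRUE(attr(l, "accel_only"))) next
      cols[[length(cols) + 1L]] <- shift_fill(rect[[ch]][[l$com_sign]], lags[i])[idx]
      s <- gain_sign(l$com_sign, l$torque_sign)
      cap <- caps[[ch]]
      lo <- c(lo, if (s > 0) 0 else -cap)
      hi <- c(hi, if (s < 0) 0 else cap)
      map[[length(map) + 1L]] <- c(i, match(ch, chans))
    }
  }
  X <- do.call(cbind, cols)
  g <- bounded_lsq(X, tau_values[idx], lo, hi, warn = warn)
  gains <- matrix(0, nrow = length(loops), ncol = 3,
                  dimnames = list(NULL, chans))
  for (k in seq_along(map)) gains[map[[k]][1], map[[k]][2]] <- g[k]
  resid <- tau_values[idx] - drop(X %*% g)
  list(gains = gains, sse = sum(resid^2))
}

fill_gains <- function(loops, gains) {
  for (i in seq_along(loops)) {
    loops[[i]]$k_d <- unname(gains[i, "d"])
    loops[[i]]$k_v <- unname(gains[i, "v"])
    loops[[i]]$k_a <- unname(gains[i, "a"])
  }
  loops
}

#' Fit the instantaneous acceleration loop alone
#'
#' Grid search over the acceleration-loop delay bounds (with local
#' refinement), computing the closed-form least-squares acceleration gain at
#' each delay, and keeping the delay/gain pair with the highest R^2 over the
#' fit window. If the acceleration regressor has no variance the gain is 0
#' and the stage R^2 is defined as 0.
#'
#' @inheritParams fit_gains_at_fixed_delays
#' @return A list with `loop` (the fitted acceleration `feedback_loop`) and
#'   `r2` (its R^2 over the fit window).
#' @export
fit_acceleration_loop <- function(com, tau, cfg = fit_config()) {
  stopifnot(inherits(com, "com_state"), inherits(tau, "time_series"))
  dt <- tau$dt
  idx <- fit_indices(tau, cfg$fit_window)
  y <- tau$values[idx]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance target: trial unusable for fitting", call. = FALSE)
  caps <- gain_caps(com, tau, idx, cfg)
  a_full <- com$a$values

  eval_lambda <- function(lam) {
    x <- shift_fill(a_full, as.integer(round(lam / dt)))[idx]
    sxx <- sum(x^2)
    if (sxx < 1e-24) return(list(k = 0, sse = sum(y^2)))
    k <- sum(x * y) / sxx
    k <- min(max(k, -caps[["a"]]), caps[["a"]])
    list(k = k, sse = sum((y - k * x)^2))
  }

  grid <- lambda_grid(cfg$lambda_bounds_accel, cfg$lambda_grid_step, dt)
  best <- NULL
  for (lam in grid) {
    cand <- eval_lambda(lam)
    if (is.null(best) || cand$sse < best$sse) best <- c(cand, lambda = lam)
  }
  for (lam in refine_grid(best$lambda, cfg, cfg$lambda_bounds_accel, dt)) {
    cand <- eval_lambda(lam)
    if (cand$sse < best$sse) best <- c(cand, lambda = lam)
  }
  r2 <- if (best$k == 0) 0 else 1 - best$sse / ss_tot
  loop <- feedback_loop(k_a = best$k, lambda_s = best$lambda,
                        com_sign = "both", torque_sign = "none")
  list(loop = loop, r2 = r2)
}

lambda_grid <- function(bounds, step, dt) {
  g <- seq(bounds[1], bounds[2], by = step)
  unique(round(round(g / dt) * dt, 12))
}

refine_grid <- function(center, cfg, bounds, dt) {
  g <- seq(center - cfg$lambda_grid_step, center + cfg$lambda_grid_step,
           by = cfg$lambda_refine_step)
  g <- g[g >= bounds[1] - 1e-12 & g <= bounds[2] + 1e-12]
  unique(round(round(g / dt) * dt, 12))
}

#' Fit a full delayed CoM feedback model to one averaged torque trace
#'
#' Runs the staged procedure on a trace that has already been averaged,
#' truncated (onset at `t = 0`) and background-subtracted. Stage 1 fits the
#' acceleration loop alone; if its R^2 exceeds `cfg$stage1_r2_stop`
#' (strictly), the residual loops stay at zero and fitting stops. Otherwise
#' the four sign-gated residual loops are fit by seeded multistart
#' coordinate descent over the residual delay grid, with all gains re-solved
#' by bounded least squares at every delay candidate (the acceleration gain
#' and delay are refit jointly unless `cfg$refit_accel` is `FALSE`). A final
#' pruning pass zeroes any loop whose presence does not improve the fit and,
#' if a loop was dropped, refits the remainder once with doubled gain caps.
#'
#' @inheritParams fit_gains_at_fixed_delays
#' @param mass_kg Participant mass (kg) for the RMSE/kg training metric;
#'   `NA` omits it.
#'
#' @return An object of class `"fit_result"`: fields `model`, `r2_train` and
#'   `rmse_per_kg_train` (computed on the full trace), `stage1_r2`,
#'   `stopped_after_stage1`, `active_parameters`, and `diagnostics` (per-loop
#'   shares of the predicted torque).
#' @export
fit_model <- function(com, tau, cfg = fit_config(), mass_kg = NA_real_) {
  stopifnot(inherits(com, "com_state"), inherits(tau, "time_series"))
  dt <- tau$dt
  idx <- fit_indices(tau, cfg$fit_window)
  y <- tau$values[idx]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance target: trial unusable for fitting", call. = FALSE)
  rect <- rectified_channels(com)
  caps <- gain_caps(com, tau, idx, cfg)

  stage1 <- fit_acceleration_loop(com, tau, cfg)
  zero_res <- lapply(residual_gatings(), function(g) {
    feedback_loop(com_sign = g$com_sign, torque_sign = g$torque_sign,
                  lambda_s = cfg$lambda_bounds_residual[1])
  })

  if (stage1$r2 > cfg$stage1_r2_stop) {
    model <- com_feedback_model(joint_id = NA_character_,
                                axis = com$axis %|na|% "y",
                                accel_loop = stage1$loop,
                                residual_loops = zero_res)
    return(finish_fit(model, com, tau, idx, stage1$r2, TRUE, mass_kg))
  }

  grid <- lambda_grid(cfg$lambda_bounds_residual, cfg$lambda_grid_step, dt)
  accel_grid <- lambda_grid(cfg$lambda_bounds_accel, cfg$lambda_grid_step, dt)
  n_loops <- 4L + as.integer(cfg$refit_accel)

  # loop skeletons used to build regressors: residual loops first, then
  # (optionally) the acceleration loop restricted to its acceleration column
  skeletons <- zero_res
  if (cfg$refit_accel) {
    acc <- feedback_loop(com_sign = "both", torque_sign = "none")
    attr(acc, "accel_only") <- TRUE
    skeletons <- c(skeletons, list(acc))
  }

  target <- if (cfg$refit_accel) tau$values else {
    tau$values - loop_output(stage1$loop, com)$values
  }

  solver <- make_gain_solver(rect, target, idx, skeletons, caps)
  objective <- function(lambdas) solver(as.integer(round(lambdas / dt)))

  run_descent <- function(start_lambdas) {
    lambdas <- start_lambdas
    best <- objective(lambdas)
    for (sweep in seq_len(cfg$max_sweeps)) {
      changed <- FALSE
      for (i in seq_len(n_loops)) {
        cand_grid <- if (cfg$refit_accel && i == n_loops) accel_grid else grid
        for (lam in cand_grid) {
          if (lam == lambdas[i]) next
          trial <- lambdas
          trial[i] <- lam
          cand <- objective(trial)
          if (cand$sse < best$sse - 1e-12) {
            best <- cand
            lambdas <- trial
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    # local refinement at sample resolution
    for (i in seq_len(n_loops)) {
      bnds <- if (cfg$refit_accel && i == n_loops) cfg$lambda_bounds_accel else cfg$lambda_bounds_residual
      for (lam in refine_grid(lambdas[i], cfg, bnds, dt)) {
        if (lam == lambdas[i]) next
        trial <- lambdas
        trial[i] <- lam
        cand <- objective(trial)
        if (cand$sse < best$sse - 1e-12) {
          best <- cand
          lambdas <- trial
        }
      }
    }
    list(lambdas = lambdas, fit = best)
  }

  mid <- grid[ceiling(length(grid) / 2)]
  starts <- list(rep(mid, 4L))
  if (cfg$multistart_count > 1L) {
    extra <- with_seed(cfg$seed, {
      lapply(seq_len(cfg$multistart_count - 1L), function(i) sample(grid, 4L, replace = TRUE))
    })
    starts <- c(starts, extra)
  }
  if (cfg$refit_accel) {
    starts <- lapply(starts, function(s) c(s, stage1$loop$lambda_s))
  }

  best <- NULL
  for (s in starts) {
    res <- run_descent(s)
    if (is.null(best) || res$fit$sse < best$fit$sse) best <- res
  }

  # parsimony: greedy backward elimination over gain columns. A term is kept
  # only if removing it (and refitting the rest) worsens the residual SSE by
  # more than `prune_tol` of its current value — a term whose contribution is
  # indistinguishable from the residual noise floor is fit noise, while a
  # genuine loop's unique contribution dwarfs the residual. This replaces
  # hand-tuned bounds as the guard against parallel loops reconstructing the
  # same response features, and is exact in the noiseless limit.
  lags <- as.integer(round(best$lambdas / dt))
  chans <- c("d", "v", "a")
  col_loop <- integer(0); col_chan <- integer(0)
  cols <- list(); lo <- numeric(0); hi <- numeric(0)
  for (i in seq_len(n_loops)) {
    l <- skeletons[[i]]
    use <- if (isTRUE(attr(l, "accel_only"))) 3L else 1:3
    for (ci in use) {
      cols[[length(cols) + 1L]] <- shift_fill(rect[[chans[ci]]][[l$com_sign]], lags[i])[idx]
      s <- gain_sign(l$com_sign, l$torque_sign)
      cap <- caps[[chans[ci]]]
      lo <- c(lo, if (s > 0) 0 else -cap)
      hi <- c(hi, if (s < 0) 0 else cap)
      col_loop <- c(col_loop, i); col_chan <- c(col_chan, ci)
    }
  }
  X <- do.call(cbind, cols)
  y <- target[idx]
  sse_for <- function(mask, cap_mult = 1) {
    if (!any(mask)) return(list(g = numeric(ncol(X)), sse = sum(y^2)))
    g <- numeric(ncol(X))
    g[mask] <- bounded_lsq(X[, mask, drop = FALSE], y, cap_mult * lo[mask],
                           cap_mult * hi[mask], warn = FALSE)
    list(g = g, sse = sum((y - drop(X %*% g))^2))
  }
  mask <- abs(best$fit$gains[cbind(col_loop, col_chan)]) > 0
  cur <- sse_for(mask)
  dropped <- FALSE
  while (any(mask)) {
    costs <- rep(Inf, length(mask))
    cands <- vector("list", length(mask))
    for (k in which(mask)) {
      trial <- mask; trial[k] <- FALSE
      cands[[k]] <- sse_for(trial)
      costs[k] <- cands[[k]]$sse - cur$sse
    }
    k_min <- which.min(costs)
    if (costs[k_min] <= cfg$prune_tol * cur$sse) {
      mask[k_min] <- FALSE
      cur <- cands[[k_min]]
      dropped <- TRUE
    } else break
  }
  if (dropped) {
    # one refit of the retained structure with doubled gain caps, in case a
    # dropped term was compensating for a bound-limited one
    wide <- sse_for(mask, cap_mult = 2)
    if (wide$sse < cur$sse - 1e-12) cur <- wide
  }
  gains <- matrix(0, n_loops, 3, dimnames = list(NULL, chans))
  gains[cbind(col_loop, col_chan)] <- cur$g
  best$fit <- list(gains = gains, sse = cur$sse)

  # snap numerically negligible gains to exact zero so the active-parameter
  # count reflects the structure actually in use
  ref_sd <- stats::sd(target[idx])
  chans <- c("d", "v", "a")
  for (i in seq_len(n_loops)) {
    for (ci in seq_along(chans)) {
      g <- best$fit$gains[i, ci]
      if (g == 0) next
      col <- shift_fill(rect[[chans[ci]]][[skeletons[[i]]$com_sign]], lags[i])[idx]
      if (abs(g) * stats::sd(col) < 1e-7 * ref_sd) best$fit$gains[i, ci] <- 0
    }
  }

  res_loops <- fill_gains(zero_res, best$fit$gains[seq_len(4L), , drop = FALSE])
  for (i in seq_len(4L)) res_loops[[i]]$lambda_s <- best$lambdas[i]
  if (cfg$refit_accel) {
    accel <- feedback_loop(k_a = best$fit$gains[n_loops, "a"],
                           lambda_s = best$lambdas[n_loops],
                           com_sign = "both", torque_sign = "none")
  } else {
    accel <- stage1$loop
  }
  model <- com_feedback_model(joint_id = NA_character_,
                              axis = com$axis %|na|% "y",
                              accel_loop = accel,
                              residual_loops = res_loops)
  finish_fit(model, com, tau, idx, stage1$r2, FALSE, mass_kg)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# assemble the fit_result: metrics on the full trace, per-loop diagnostics
finish_fit <- function(model, com, tau, idx, stage1_r2, stopped, mass_kg) {
  pred <- predict_torque(model, com)
  r2 <- compute_r2(tau, pred)
  rmse <- if (is.finite(mass_kg)) compute_rmse_per_kg(tau, pred, mass_kg) else NA_real_
  loops <- c(list(accel = model$accel_loop),
             stats::setNames(model$residual_loops,
                             vapply(model$residual_loops,
                                    function(l) paste0("com", l$com_sign, "_tau", l$torque_sign),
                                    character(1))))
  sds <- vapply(loops, function(l) stats::sd(loop_output(l, com)$values[idx]), numeric(1))
  share <- if (sum(sds) > 0) sds / sum(sds) else sds
  structure(
    list(model = model, r2_train = r2, rmse_per_kg_train = rmse,
         stage1_r2 = stage1_r2, stopped_after_stage1 = stopped,
         active_parameters = count_active_parameters(model),
         diagnostics = list(loop_share = share)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> R2 %.4f%s | stage-1 R2 %.4f%s | %d active parameters\n",
    x$r2_train,
    if (is.finite(x$rmse_per_kg_train)) sprintf(", RMSE %.4f Nm/kg", x$rmse_per_kg_train) else "",
    x$stage1_r2,
    if (x$stopped_after_stage1) " (stopped after stage 1)" else "",
    x$active_parameters
  ))
  print(x$model)
  invisible(x)
}
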