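# Post-hoc analyses of crash predictions: where the classifier fails,
# what destabilizing deflections have to do with it, where the device was
# heading, and whether a warned crash was still physically avoidable.

#' Misclassification rates stratified by peak angular position
#'
#' Bins windows by the farthest the device was from the balance point
#' within the data window (max |position|) and reports, per bin, the rate
#' at which crash windows were predicted non-crash (missed crashes, false
#' negatives) and non-crash windows were predicted crash (false alarms).
#'
#' @param predictions `prediction_records` (with `max_abs_theta`).
#' @param threshold decision threshold (predicted crash iff score >=
#'   threshold), e.g. the one chosen by [precision_at_recall()].
#' @param bin_edges increasing bin edges over \[0, crash boundary\] in deg
#'   (default 6 bins of 10 deg).
#' @return data.frame: `bin_lo`, `bin_hi`, `n_crash`, `fn_rate`,
#'   `n_noncrash`, `fp_rate` (rates `NA` where a bin holds no samples of
#'   that class).
#' @export
misclassification_by_position <- function(predictions, threshold,
                                          bin_edges = seq(0, 60, by = 10)) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  cl <- classify_predictions(predictions, threshold)
  bin <- cut(cl$max_abs_theta, breaks = bin_edges, include.lowest = TRUE,
             right = FALSE)
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1])
  out$n_crash <- as.integer(tapply(cl$label == 1, bin, sum, default = 0L))
  out$fn_rate <- as.numeric(tapply(seq_len(nrow(cl)), bin, function(i) {
    pos <- cl$label[i] == 1
    if (!any(pos)) return(NA_real_)
    mean(cl$type[i][pos] == "FN")
  }))
  out$n_noncrash <- as.integer(tapply(cl$label == 0, bin, sum, default = 0L))
  out$fp_rate <- as.numeric(tapply(seq_len(nrow(cl)), bin, function(i) {
    neg <- cl$label[i] == 0
    if (!any(neg)) return(NA_real_)
    mean(cl$type[i][neg] == "FP")
  }))
  out
}

# samples of `trial` falling in the look-ahead interval (end, end+advance]
advance_interval_samples <- function(trial, end_time, advance_s) {
  s <- trial$samples
  s[s$t > end_time + 1e-9 & s$t <= end_time + advance_s + 1e-9, ,
    drop = FALSE]
}

trial_lookup <- function(trials) {
  keys <- vapply(trials, trial_key_of, character(1))
  if (anyDuplicated(keys)) stop("duplicate trial keys in trials list")
  names(trials) <- keys
  trials
}

#' Destabilizing-deflection rates by prediction type
#'
#' For each prediction type (FN, FP, TN, TP at `threshold`), the fraction
#' of windows whose look-ahead interval contains destabilizing joystick
#' deflection time steps -- the unexpected commands, invisible to the
#' model, that explain missed crashes near the balance point.
#'
#' @param predictions `prediction_records` with `trial_key` and `end_time`.
#' @param trials list of the `trial_record`s the windows came from.
#' @param advance_ms look-ahead duration used for labeling, ms.
#' @param threshold decision threshold.
#' @param how `"any"` (default): a window counts if >= 1 look-ahead step is
#'   destabilizing; `"fraction"`: mean destabilizing fraction of look-ahead
#'   steps per window, averaged within type.
#' @return data.frame with `type` (FN/FP/TN/TP), `n`, `djd_rate`.
#' @export
djd_rate_by_prediction_type <- function(predictions, trials, advance_ms,
                                        threshold, how = c("any", "fraction")) {
  how <- match.arg(how)
  cl <- classify_predictions(predictions, threshold)
  trials <- trial_lookup(trials)
  adv <- advance_ms / 1000
  per_window <- vapply(seq_len(nrow(cl)), function(i) {
    tr <- trials[[cl$trial_key[i]]]
    if (is.null(tr)) stop("trial ", cl$trial_key[i], " not supplied")
    seg <- advance_interval_samples(tr, cl$end_time[i], adv)
    if (nrow(seg) == 0) return(0)
    d <- djd_flag(seg$theta, seg$omega, seg$joystick)
    if (how == "any") as.numeric(any(d == 1)) else mean(d)
  }, numeric(1))
  agg <- tapply(per_window, cl$type, mean, default = NA_real_)
  data.frame(type = names(agg),
             n = as.integer(table(cl$type)[names(agg)]),
             djd_rate = as.numeric(agg),
             row.names = NULL)
}

#' State-density maps by prediction type
#'
#' Two-dimensional histograms of (position, velocity) over every time step
#' in the look-ahead interval of each window, normalized to unit mass per
#' prediction type.  High-|position|, high-|velocity| mass under false and
#' true positives shows the model flagging genuinely dangerous motion.
#'
#' @inheritParams djd_rate_by_prediction_type
#' @param theta_breaks,omega_breaks histogram bin edges (defaults cover the
#'   device limits, 24 bins each).
#' @return A list with `breaks` and, per type, a density matrix
#'   (`theta` rows x `omega` columns) summing to 1 (or all-`NA` when the
#'   type has no mass).
#' @export
state_density_by_type <- function(predictions, trials, advance_ms, threshold,
                                  theta_breaks = seq(-60, 60, length.out = 25),
                                  omega_breaks = seq(-300, 300, length.out = 25)) {
  cl <- classify_predictions(predictions, threshold)
  trials <- trial_lookup(trials)
  adv <- advance_ms / 1000
  counts <- lapply(levels(cl$type), function(tp)
    matrix(0, length(theta_breaks) - 1, length(omega_breaks) - 1))
  names(counts) <- levels(cl$type)
  for (i in seq_len(nrow(cl))) {
    tr <- trials[[cl$trial_key[i]]]
    seg <- advance_interval_samples(tr, cl$end_time[i], adv)
    if (nrow(seg) == 0) next
    bi <- findInterval(seg$theta, theta_breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    bj <- findInterval(seg$omega, omega_breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    tp <- as.character(cl$type[i])
    for (k in seq_along(bi)) {
      counts[[tp]][bi[k], bj[k]] <- counts[[tp]][bi[k], bj[k]] + 1
    }
  }
  dens <- lapply(counts, function(m) {
    tot <- sum(m)
    if (tot == 0) m * NA_real_ else m / tot
  })
  c(list(breaks = list(theta = theta_breaks, omega = omega_breaks)), dens)
}

#' Compute the recoverable region by extremal-policy reachability
#'
#' A state (position, velocity) is recoverable when some admissible
#' joystick policy (|u| <= 1) keeps the device inside the crash boundaries
#' over the horizon.  For this one-dimensional monotone system, the
#' extremal policy -- full deflection opposing the position (opposing the
#' velocity at 0 deg) -- is optimal: if it cannot save a state, nothing
#' can.  The region is computed by simulating that policy from every grid
#' cell with the same integrator and clamps as the device itself.
#'
#' @param params a [sim_params()] object (the control authority is
#'   `joystick_gain`; the region shrinks as the gain does).
#' @param theta_step,omega_step grid resolution, deg and deg/s.
#' @param horizon simulated recovery horizon, s (default 10, ample for the
#'   worst recoverable state).
#' @return A `recoverable_region`: list with `theta` and `omega` cell
#'   centers, logical matrix `recoverable` (theta x omega), `params`,
#'   `horizon`.
#' @export
compute_recoverable_region <- function(params = sim_params(),
                                       theta_step = 2, omega_step = 10,
                                       horizon = 10) {
  th_c <- seq(-params$crash_boundary, params$crash_boundary, by = theta_step)
  om_c <- seq(-params$velocity_limit, params$velocity_limit, by = omega_step)
  g <- expand.grid(theta = th_c, omega = om_c)
  alive <- abs(g$theta) < params$crash_boundary
  theta <- g$theta; omega <- g$omega
  n_steps <- ceiling(horizon / params$dt)
  for (s in seq_len(n_steps)) {
    if (!any(alive)) break
    u <- -sign(theta)
    u[u == 0] <- -sign(omega[u == 0])
    st <- vec_step(theta[alive], omega[alive], u[alive], params)
    theta[alive] <- st$theta
    omega[alive] <- st$omega
    crashed <- alive
    crashed[alive] <- abs(st$theta) >= params$crash_boundary
    alive <- alive & !crashed
  }
  structure(list(
    theta = th_c, omega = om_c,
    recoverable = matrix(alive, nrow = length(th_c),
                         dimnames = list(NULL, NULL)),
    params = params, horizon = horizon,
    theta_step = theta_step, omega_step = omega_step
  ), class = "recoverable_region")
}

# vectorized variant of mars_step (same semantics over state vectors)
vec_step <- function(theta, omega, u, params) {
  omega <- omega + params$joystick_gain * u
  dt <- params$dt; vl <- params$velocity_limit
  f_om <- function(om) clamp(om, vl)
  f_ac <- function(th) pendulum_accel(th, params)
  k1t <- f_om(omega);                     k1o <- f_ac(theta)
  k2t <- f_om(omega + dt / 2 * k1o);      k2o <- f_ac(theta + dt / 2 * k1t)
  k3t <- f_om(omega + dt / 2 * k2o);      k3o <- f_ac(theta + dt / 2 * k2t)
  k4t <- f_om(omega + dt * k3o);          k4o <- f_ac(theta + dt * k3t)
  list(theta = theta + dt / 6 * (k1t + 2 * k2t + 2 * k3t + k4t),
       omega = clamp(omega + dt / 6 * (k1o + 2 * k2o + 2 * k3o + k4o), vl))
}

#' Recoverability of arbitrary states
#'
#' Nearest-cell lookup into a [compute_recoverable_region()] grid; states
#' at or beyond the crash boundary are unrecoverable by definition.
#'
#' @param region a `recoverable_region`.
#' @param theta,omega state vectors (deg, deg/s).
#' @return Logical vector.
#' @export
is_recoverable <- function(region, theta, omega) {
  stopifnot(inherits(region, "recoverable_region"), length(theta) == length(omega))
  bd <- region$params$crash_boundary
  i <- round((theta - region$theta[1]) / region$theta_step) + 1
  j <- round((omega - region$omega[1]) / region$omega_step) + 1
  i <- pmin(pmax(i, 1), length(region$theta))
  j <- pmin(pmax(j, 1), length(region$omega))
  ok <- region$recoverable[cbind(i, j)]
  ok & abs(theta) < bd
}

#' @export
print.recoverable_region <- function(x, ...) {
  cat(sprintf(
    "recoverable_region: %d x %d grid, %.1f%% recoverable (gain %g, horizon %g s)\n",
    length(x$theta), length(x$omega), 100 * mean(x$recoverable),
    x$params$joystick_gain, x$horizon))
  invisible(x)
}

#' States a fixed time before each crash
#'
#' For every crash in `trials`, the device state at the sample nearest to
#' (at or before) `before_s` seconds ahead of the impact, never leaving the
#' crash's own episode; crashes whose episode is shorter than `before_s`
#' contribute their episode's first sample.
#'
#' @param trials list of `trial_record`s.
#' @param before_s look-back from impact, s (0 = the impact state itself).
#' @return data.frame `theta`, `omega`, `t`, `crash_time`, `trial_key`.
#' @export
crash_states <- function(trials, before_s) {
  stopifnot(before_s >= 0)
  out <- NULL
  for (tr in trials) {
    eps <- extract_episodes(tr)
    for (e in eps) {
      if (e$end_cause != "CRASH") next
      k <- which(e$time_to_crash >= before_s - 1e-9)
      k <- if (length(k)) k[length(k)] else 1L
      out <- rbind(out, data.frame(
        theta = e$samples$theta[k], omega = e$samples$omega[k],
        t = e$samples$t[k], crash_time = e$crash_time,
        trial_key = trial_key_of(e)))
    }
  }
  out
}

#' Fraction of crashes still savable as warning time elapses
#'
#' A crash predicted `advance_ms` ahead leaves `advance_ms - elapsed` of
#' margin once `elapsed` ms have passed (reaction time, decision latency).
#' For each elapsed offset this reports the fraction of crashes whose state
#' at that remaining margin lies in the recoverable region.  At
#' `elapsed = advance_ms` the state is the impact state at the boundary, so
#' the savable fraction is 0 by definition.
#'
#' @param trials list of `trial_record`s providing the crashes.
#' @param region a [compute_recoverable_region()] result.
#' @param elapsed_ms elapsed offsets, ms (each in \[0, advance_ms\]).
#' @param advance_ms the prediction look-ahead, ms.
#' @return A `savability_report` data.frame: `elapsed_ms`, `n_crashes`,
#'   `pct_savable` (percent).
#' @export
savable_fraction <- function(trials, region,
                             elapsed_ms = c(0, 200, 400, 600, 800),
                             advance_ms = 800) {
  if (any(elapsed_ms < 0 | elapsed_ms > advance_ms)) {
    stop("elapsed offsets must lie in [0, advance_ms]")
  }
  rows <- lapply(elapsed_ms, function(e) {
    cs <- crash_states(trials, before_s = (advance_ms - e) / 1000)
    if (is.null(cs)) stop("no crashes in the supplied trials")
    data.frame(elapsed_ms = e, n_crashes = nrow(cs),
               pct_savable = 100 * mean(is_recoverable(region, cs$theta,
                                                       cs$omega)))
  })
  structure(do.call(rbind, rows), class = c("savability_report", "data.frame"))
}
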