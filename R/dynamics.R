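# Inverted-pendulum device dynamics: RK4 integration with device clamps,
# crash detection at the boundary, and post-crash reset.

DEG2RAD <- pi / 180

# Clamped pendulum angular acceleration (deg/s^2).  theta in degrees; the
# sine argument is converted to radians so that kP = 600 linearizes to
# ~0.515 Hz.  The acceleration clamp is applied inside the ODE right-hand
# side: the stated limits are device limits, so they hold continuously.
pendulum_accel <- function(theta, params) {
  a <- params$pendulum_constant * sin(theta * DEG2RAD)
  pmin(pmax(a, -params$acceleration_limit), params$acceleration_limit)
}

#' Small-angle natural frequency of the device
#'
#' Linearizing `theta_ddot = kP * sin(theta)` (theta in degrees, sine taken
#' in radians) about the unstable equilibrium gives a characteristic rate
#' `sqrt(kP * pi/180)` rad/s, i.e. a frequency `sqrt(kP * pi/180) / (2*pi)`
#' Hz.  With the default pendulum constant of 600 deg/s^2 this is 0.515 Hz
#' (0.52 rounded), which sets the time scale a pilot must beat.
#'
#' @param params a [sim_params()] object.
#' @return Frequency in Hz.
#' @examples
#' natural_frequency(sim_params())         # 0.515
#' @export
natural_frequency <- function(params = sim_params()) {
  stopifnot(params$pendulum_constant > 0)
  sqrt(params$pendulum_constant * DEG2RAD) / (2 * pi)
}

#' Advance the balancing device by one timestep
#'
#' Applies the joystick coupling and integrates the pendulum one `dt`.  The
#' joystick adds a discrete velocity increment `joystick_gain * u` once per
#' step, before integration; the pendulum term is then advanced by classical
#' RK4 on `theta_dot = omega`, `omega_dot = clamp(kP sin theta)`.  Angular
#' velocity is clamped to the device limit after each RK4 stage state and
#' after the step.
#'
#' @param state named list or vector with `theta` (deg), `omega` (deg/s).
#' @param joystick joystick deflection in [-1, 1].
#' @param params a [sim_params()] object.
#' @return list with the new `theta` and `omega`.
#' @examples
#' mars_step(list(theta = 10, omega = 0), 0, sim_params())
#' @export
mars_step <- function(state, joystick, params = sim_params()) {
  theta <- state$theta
  omega <- state$omega
  if (!is.finite(theta) || !is.finite(omega) || !is.finite(joystick)) {
    stop("mars_step: non-finite state or joystick input (theta=", theta,
         ", omega=", omega, ", joystick=", joystick, ")")
  }
  if (joystick < -1 || joystick > 1) {
    stop("mars_step: joystick deflection must be in [-1, 1], got ", joystick)
  }
  omega <- omega + params$joystick_gain * joystick
  st <- rk4_pendulum(theta, omega, params)
  st$omega <- clamp(st$omega, params$velocity_limit)
  st
}

clamp <- function(x, lim) pmin(pmax(x, -lim), lim)

# One RK4 step of the pendulum-only dynamics.  Velocity is clamped at each
# stage evaluation so slope estimates never exceed the device limit.
rk4_pendulum <- function(theta, omega, params) {
  dt <- params$dt
  vl <- params$velocity_limit
  f <- function(th, om) {
    om <- clamp(om, vl)
    c(om, pendulum_accel(th, params))
  }
  k1 <- f(theta, omega)
  k2 <- f(theta + dt / 2 * k1[1], omega + dt / 2 * k1[2])
  k3 <- f(theta + dt / 2 * k2[1], omega + dt / 2 * k2[2])
  k4 <- f(theta + dt * k3[1], omega + dt * k3[2])
  list(theta = theta + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]),
       omega = omega + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]))
}

#' Crash detection at the boundary
#'
#' A crash occurs when the angular position reaches or exceeds the crash
#' boundary.  The recorded position is clipped to the boundary (overshoot
#' within a step is an integration artifact, not a device state).
#'
#' @param state list with `theta` (deg) and optionally `t` (s).
#' @param params a [sim_params()] object.
#' @return `NULL` if no crash; otherwise a list with `theta` (clipped to
#'   `+/-crash_boundary`) and `t` (if present in `state`).
#' @export
detect_crash <- function(state, params = sim_params()) {
  if (abs(state$theta) < params$crash_boundary) return(NULL)
  list(theta = clamp(state$theta, params$crash_boundary),
       t = state$t)
}

#' Simulate one balancing trial
#'
#' Alternates BALANCING and RESETTING phases until the cumulative
#' human-controlled balancing time reaches `trial_balance_seconds`.  During
#' BALANCING the supplied pilot callback commands the joystick each step;
#' reaching `+/-crash_boundary` records a crash, after which the device
#' RESETS toward 0 deg at `reset_rate` with the joystick disabled.  Reset
#' time does not count toward the balancing total.
#'
#' @param pilot a controller: a function `f(history)` returning a joystick
#'   deflection in [-1, 1].  `history` is a list with vectors `t`, `theta`,
#'   `omega`, `joystick`, `control_enabled` of the most recent samples (up to
#'   128), `i` the index of the current sample within those vectors, and
#'   `abs_i` its absolute sample index in the trial.  Out-of-range commands
#'   are clipped with a warning.  See [make_pilot()].
#' @param params a [sim_params()] object.
#' @param seed integer seed; identical seeds give bit-identical trials.
#' @param theta0,omega0 initial state (deg, deg/s).
#' @return A `trial_record`: list with `samples` (data.frame `t`, `theta`,
#'   `omega`, `joystick`, `control_enabled`), `crash_times` (s),
#'   `cumulative_balance_time` (s), `params`, and `seed`.
#' @examples
#' tr <- simulate_trial(function(h) 0, sim_params(trial_balance_seconds = 5),
#'                      seed = 1, theta0 = 0.1)
#' length(tr$crash_times)
#' @export
simulate_trial <- function(pilot, params = sim_params(), seed = 1L,
                           theta0 = 0, omega0 = 0) {
  stopifnot(is.function(pilot))
  set.seed(as.integer(seed))
  dt <- params$dt
  n_balance <- round(params$trial_balance_seconds / dt)

  # generous preallocation: balancing steps + worst-case resets
  cap <- n_balance + 64L
  t_v <- numeric(cap); th_v <- numeric(cap); om_v <- numeric(cap)
  js_v <- numeric(cap); ce_v <- logical(cap)
  crash_times <- numeric(0)

  hist <- new.env(parent = emptyenv())

  grow <- function(k) {
    if (k <= cap) return(invisible(NULL))
    newcap <- max(cap * 2L, k)
    length(t_v) <<- newcap; length(th_v) <<- newcap; length(om_v) <<- newcap
    length(js_v) <<- newcap; length(ce_v) <<- newcap
    cap <<- newcap
  }

  theta <- theta0; omega <- omega0
  t <- 0; i <- 1L
  balance_steps <- 0L
  phase <- "BALANCING"
  warned_clip <- FALSE

  # emit the initial sample
  t_v[1] <- 0; th_v[1] <- theta; om_v[1] <- omega
  js_v[1] <- 0; ce_v[1] <- TRUE

  history <- function() {
    lo <- max(1L, i - 127L)
    idx <- lo:i
    list(t = t_v[idx], theta = th_v[idx], omega = om_v[idx],
         joystick = js_v[idx], control_enabled = ce_v[idx],
         i = i - lo + 1L, abs_i = i)
  }

  while (balance_steps < n_balance) {
    if (phase == "BALANCING") {
      u <- pilot(history())
      if (!is.numeric(u) || length(u) != 1L || !is.finite(u)) {
        stop("pilot returned a non-finite or non-scalar joystick command")
      }
      if (u < -1 || u > 1) {
        if (!warned_clip) {
          warning("pilot command outside [-1, 1]; clipping (warned once)")
          warned_clip <- TRUE
        }
        u <- clamp(u, 1)
      }
      js_v[i] <- u                     # command held over [t, t+dt)
      st <- mars_step(list(theta = theta, omega = omega), u, params)
      theta <- st$theta; omega <- st$omega
      t <- t + dt
      balance_steps <- balance_steps + 1L
      i <- i + 1L; grow(i)
      crash <- detect_crash(list(theta = theta, t = t), params)
      if (!is.null(crash) && balance_steps < n_balance) {
        theta <- crash$theta               # impact omega kept in the sample
        crash_times <- c(crash_times, t)
        t_v[i] <- t; th_v[i] <- theta; om_v[i] <- omega
        js_v[i] <- 0; ce_v[i] <- TRUE  # crash sample: last balancing sample
        phase <- "RESETTING"
      } else {
        if (!is.null(crash)) {         # crash on the very last step
          theta <- crash$theta
          crash_times <- c(crash_times, t)
        }
        t_v[i] <- t; th_v[i] <- theta; om_v[i] <- omega
        js_v[i] <- 0; ce_v[i] <- TRUE
      }
    } else {                           # RESETTING: move toward 0 at reset_rate
      step_mag <- params$reset_rate * dt
      theta <- if (abs(theta) <= step_mag) 0 else theta - sign(theta) * step_mag
      omega <- 0
      t <- t + dt
      i <- i + 1L; grow(i)
      t_v[i] <- t; th_v[i] <- theta; om_v[i] <- omega
      js_v[i] <- 0; ce_v[i] <- FALSE
      if (theta == 0) phase <- "BALANCING"
    }
  }

  samples <- data.frame(
    t = t_v[seq_len(i)],
    theta = th_v[seq_len(i)],
    omega = om_v[seq_len(i)],
    joystick = js_v[seq_len(i)],
    control_enabled = ce_v[seq_len(i)]
  )
  structure(list(
    samples = samples,
    crash_times = crash_times,
    cumulative_balance_time = balance_steps * dt,
    params = params,
    seed = as.integer(seed)
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial_record: %d samples, %.1f s balancing, %d crash%s (seed %d)\n",
              nrow(x$samples), x$cumulative_balance_time,
              length(x$crash_times),
              if (length(x$crash_times) == 1) "" else "es", x$seed))
  invisible(x)
}
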