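#' Physical and task constants of the MARS balancing analog
#'
#' Bundles every constant of the simulated device: a one-axis rotating chair
#' programmed as an inverted pendulum about the direction of balance (DOB,
#' 0 degrees).  Angular acceleration follows `theta_ddot = kP * sin(theta)`
#' (state kept in degrees, the sine argument converted to radians), clamped to
#' the device's acceleration limit; angular velocity is clamped after every
#' integrator sub-step.  Crashes occur at `+/-crash_boundary`; after a crash
#' the device resets toward 0 at `reset_rate` with the joystick disabled.
#'
#' @param pendulum_constant angular acceleration scale kP, deg/s^2.  The
#'   default 600 gives a small-angle natural frequency of about 0.52 Hz.
#' @param crash_boundary crash boundary, deg (must be <= 90).
#' @param velocity_limit angular velocity clamp, deg/s.
#' @param acceleration_limit pendulum angular acceleration clamp, deg/s^2.
#' @param dt integration timestep, s (must be in (0, 0.1]).
#' @param joystick_gain velocity increment added per step at full joystick
#'   deflection, deg/s.  The default 6 deg/s per 0.02-s step corresponds to
#'   about 300 deg/s^2 of control authority: ample to arrest the pendulum
#'   well inside the boundaries, yet crashes remain easy under poor control.
#' @param reset_rate post-crash reset speed toward 0 deg, deg/s.
#' @param trial_balance_seconds cumulative human-controlled balancing time
#'   per trial, s (reset intervals excluded).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' natural_frequency(p)   # ~0.515 Hz
#' @export
sim_params <- function(pendulum_constant = 600,
                       crash_boundary = 60,
                       velocity_limit = 300,
                       acceleration_limit = 180,
                       dt = 0.02,
                       joystick_gain = 6,
                       reset_rate = 5,
                       trial_balance_seconds = 100) {
  p <- list(
    pendulum_constant = pendulum_constant,
    crash_boundary = crash_boundary,
    velocity_limit = velocity_limit,
    acceleration_limit = acceleration_limit,
    dt = dt,
    joystick_gain = joystick_gain,
    reset_rate = reset_rate,
    trial_balance_seconds = trial_balance_seconds
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("sim_params fields must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (any(unlist(p) <= 0)) {
    stop("sim_params fields must be strictly positive: ",
         paste(names(p)[unlist(p) <= 0], collapse = ", "))
  }
  if (p$crash_boundary > 90) stop("crash_boundary must be <= 90 degrees")
  if (p$dt > 0.1) stop("dt must be in (0, 0.1] seconds")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("MARS simulation parameters\n")
  cat(sprintf("  pendulum constant : %g deg/s^2 (f0 = %.3f Hz)\n",
              x$pendulum_constant, natural_frequency(x)))
  cat(sprintf("  crash boundary    : +/-%g deg\n", x$crash_boundary))
  cat(sprintf("  limits            : |omega| <= %g deg/s, |accel| <= %g deg/s^2\n",
              x$velocity_limit, x$acceleration_limit))
  cat(sprintf("  timestep          : %g s, joystick gain %g deg/s per step\n",
              x$dt, x$joystick_gain))
  cat(sprintf("  reset rate        : %g deg/s; trial = %g s of balancing\n",
              x$reset_rate, x$trial_balance_seconds))
  invisible(x)
}

#' Parameters of the synthetic disoriented pilot
#'
#' A stateful PD-like controller whose "disorientation" is modelled as leaky
#' integration of the position estimate (absolute position sense decays
#' toward 0 at `position_leak` per second, producing the characteristic
#' positional drift), a sensorimotor reaction delay, noisy velocity
#' perception, discrete 1-2 Hz command updates, and occasional sign-flipped
#' (destabilizing) deflections.
#'
#' @param position_leak 1/s, decay rate of the internal position estimate
#'   toward 0.  0 = veridical position sense; larger values produce stronger
#'   drift away from the balance point.
#' @param estimate_noise_sd deg/s, SD of white noise on perceived velocity.
#' @param reaction_delay s, sensorimotor delay applied to all percepts
#'   (default 0.4, a typical delay for choice joystick responses).
#' @param kp,kd proportional/derivative gains applied to the position and
#'   velocity estimates (dimensionless; the command is
#'   `-(kp * theta_hat + kd * omega_hat)` clipped to [-1, 1]).
#' @param deflection_rate_hz mean rate of discrete command updates (Poisson
#'   clock), matching the observed 1-2 Hz full-deflection rate.
#' @param sign_error_prob probability that a freshly issued command has its
#'   sign flipped, i.e. is destabilizing.
#' @param prediction fraction (0..1) of the reaction delay the pilot
#'   compensates with an internal forward model of the device (efference-copy
#'   prediction).  This is the proficiency axis: the unstable pole times the
#'   delay exceeds 1 here, so purely delayed feedback cannot stabilize the
#'   device and only predictive pilots balance for long stretches.
#'
#' @return An object of class `pilot_params`.
#' @seealso [make_pilot()], [make_cohort()]
#' @export
pilot_params <- function(position_leak = 0.3,
                         estimate_noise_sd = 5,
                         reaction_delay = 0.4,
                         kp = 0.05,
                         kd = 0.04,
                         deflection_rate_hz = 1.5,
                         sign_error_prob = 0.15,
                         prediction = 0.7) {
  p <- list(
    position_leak = position_leak,
    estimate_noise_sd = estimate_noise_sd,
    reaction_delay = reaction_delay,
    kp = kp,
    kd = kd,
    deflection_rate_hz = deflection_rate_hz,
    sign_error_prob = sign_error_prob,
    prediction = prediction
  )
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("pilot_params fields must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (sign_error_prob < 0 || sign_error_prob > 1) {
    stop("sign_error_prob must be in [0, 1]")
  }
  if (prediction < 0 || prediction > 1) {
    stop("prediction must be in [0, 1]")
  }
  if (reaction_delay < 0) stop("reaction_delay must be >= 0")
  if (kp < 0 || kd < 0) stop("gains kp, kd must be >= 0")
  if (position_leak < 0) stop("position_leak must be >= 0")
  if (estimate_noise_sd < 0) stop("estimate_noise_sd must be >= 0")
  if (deflection_rate_hz <= 0) stop("deflection_rate_hz must be > 0")
  structure(p, class = "pilot_params")
}
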