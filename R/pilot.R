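# Synthetic disoriented pilot: a stateful, delayed controller driven by a
# leaky-integrated position estimate and an internal forward model.
#
# Design note: with pendulum constant 600 deg/s^2 the unstable pole is
# lambda = sqrt(kP*pi/180) ~ 3.24 /s, so a 0.4-s sensorimotor delay gives
# lambda*tau ~ 1.3 > 1: no purely delayed state feedback can stabilize the
# loop.  Skilled operators overcome this with predictive compensation -- an
# internal model of the device driven by an efference copy of their own
# recent commands.  The `prediction` parameter (0..1, the fraction of the
# delay compensated this way) is therefore the pilot's proficiency axis;
# disorientation degrades the loop through position-estimate leak, velocity
# noise and sign-flipped (destabilizing) deflections.

#' Create a stateful synthetic pilot controller
#'
#' Returns a closure usable as the `pilot` argument of [simulate_trial()].
#' Internally the pilot:
#' * perceives angular velocity with a sensorimotor `reaction_delay` and
#'   additive Gaussian noise (`estimate_noise_sd`),
#' * integrates perceived velocity into a position estimate that leaks
#'   toward 0 at `position_leak` per second (no absolute position sense in
#'   the disorienting condition: this produces positional drift),
#' * compensates a fraction `prediction` of its delay by running an internal
#'   forward model of the pendulum fed by an efference copy of its own
#'   recent joystick commands,
#' * at Poisson-clocked decision instants (base rate `deflection_rate_hz`,
#'   accelerated when perceived speed is high) issues a new held command
#'   `-(kp * theta_hat + kd * omega_hat)` clipped to \[-1, 1\],
#' * flips the command's sign with probability `sign_error_prob`, producing
#'   destabilizing joystick deflections.
#'
#' The pilot's internal state resets whenever the previous sample was under
#' automatic reset (the operator restarts from a known 0 deg position).
#' Randomness comes from the session RNG, so [simulate_trial()]'s seed makes
#' whole trials reproducible.
#'
#' @param pilot_par a [pilot_params()] object.
#' @param sim_par the [sim_params()] the pilot will fly under.
#' @return A function `f(history) -> joystick deflection in [-1, 1]`.
#' @examples
#' p <- make_pilot(pilot_params(), sim_params())
#' tr <- simulate_trial(p, sim_params(trial_balance_seconds = 20), seed = 7)
#' @export
make_pilot <- function(pilot_par = pilot_params(), sim_par = sim_params()) {
  prediction <- pilot_par$prediction
  dt <- sim_par$dt
  delay_steps <- as.integer(round(pilot_par$reaction_delay / dt))
  p_update <- min(1, pilot_par$deflection_rate_hz * dt)
  kP <- sim_par$pendulum_constant
  gain <- sim_par$joystick_gain
  alim <- sim_par$acceleration_limit
  urgency_scale <- 10   # deg/s of perceived speed that doubles the decision rate

  theta_hat <- 0
  u_held <- 0

  function(history) {
    i <- history$i
    if (i > 1L && !history$control_enabled[i - 1L]) {
      # fresh start after an automatic reset: known 0 deg position
      theta_hat <<- 0
      u_held <<- 0
    }
    j <- max(1L, i - delay_steps)
    omega_d <- history$omega[j] +
      if (pilot_par$estimate_noise_sd > 0)
        stats::rnorm(1, 0, pilot_par$estimate_noise_sd) else 0
    theta_hat <<- theta_hat +
      (omega_d - pilot_par$position_leak * theta_hat) * dt

    # forward internal model over the compensated part of the delay, driven
    # by the efference copy of the commands actually issued in that interval
    n_fwd <- as.integer(round(prediction * (i - j)))
    theta_p <- theta_hat
    omega_p <- omega_d
    if (n_fwd > 0L) {
      for (k in (i - n_fwd):(i - 1L)) {
        omega_p <- omega_p + gain * history$joystick[k]
        a <- max(-alim, min(alim, kP * sin(theta_p * pi / 180)))
        theta_p <- theta_p + omega_p * dt
        omega_p <- omega_p + a * dt
      }
    }

    p_now <- min(1, p_update * (1 + abs(omega_p) / urgency_scale))
    if (stats::runif(1) < p_now) {
      u <- -(pilot_par$kp * theta_p + pilot_par$kd * omega_p)
      u <- min(1, max(-1, u))
      if (pilot_par$sign_error_prob > 0 &&
          stats::runif(1) < pilot_par$sign_error_prob) {
        u <- -u
      }
      u_held <<- u
    }
    u_held
  }
}

#' Generate a cohort of synthetic pilots spanning a difficulty range
#'
#' Produces `n_pilots` parameter sets whose disorientation severity
#' (position-estimate leak, velocity-perception noise, destabilizing-command
#' probability, loss of predictive delay compensation) increases across the
#' cohort, emulating a participant pool that spans proficient,
#' rarely-crashing operators to non-proficient, frequently-crashing ones.
#' Difficulty grid points are spaced cubically so most of the cohort is
#' mildly impaired and a minority is severely impaired; with the defaults a
#' cohort averages roughly the per-trial episode count of the reference
#' participant pool (about 16-19 episodes per 100-s trial) while individual
#' pilots range from a couple of crashes per trial to over fifty.  Mild
#' multiplicative jitter keeps pilots at the same difficulty distinct.
#'
#' @param n_pilots number of pilots (>= 1).
#' @param difficulty length-2 numeric, the \[0, 1\] difficulty range to span
#'   (0 = mildest, 1 = most disoriented).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return List of [pilot_params()] objects, each with a `prediction` field
#'   and attributes `pilot_id` and `difficulty`.
#' @examples
#' cohort <- make_cohort(4, seed = 1)
#' sapply(cohort, function(p) p$sign_error_prob)
#' @export
make_cohort <- function(n_pilots, difficulty = c(0, 1), seed = 1L) {
  stopifnot(n_pilots >= 1, length(difficulty) == 2,
            all(difficulty >= 0), all(difficulty <= 1),
            difficulty[2] >= difficulty[1])
  set.seed(as.integer(seed))
  u <- if (n_pilots == 1) 0.5 else seq(0, 1, length.out = n_pilots)
  d <- difficulty[1] + (difficulty[2] - difficulty[1]) * u^3
  jit <- function(x, frac = 0.15) x * stats::runif(length(x), 1 - frac, 1 + frac)
  lapply(seq_len(n_pilots), function(k) {
    q <- d[k]^2
    pp <- pilot_params(
      position_leak = jit(0.05 + 0.5 * q),
      estimate_noise_sd = jit(0.5 + 8 * q),
      reaction_delay = 0.4,
      kp = jit(0.05),
      kd = jit(0.04),
      deflection_rate_hz = stats::runif(1, 1, 2),
      sign_error_prob = min(1, jit(0.01 + 0.3 * q)),
      prediction = max(0, min(1, jit(1 - 0.7 * d[k], frac = 0.05)))
    )
    attr(pp, "pilot_id") <- k
    attr(pp, "difficulty") <- d[k]
    pp
  })
}

#' Simulate all trials of a cohort
#'
#' Runs `n_trials` balancing trials for every pilot in `cohort`, with trial
#' seeds derived reproducibly from `seed`.
#'
#' @param cohort list of [pilot_params()] from [make_cohort()].
#' @param n_trials trials per pilot.
#' @param sim_par a [sim_params()] object.
#' @param seed integer base seed.
#' @return List of `trial_record`s; each carries attributes `pilot_id` and
#'   `trial_id`.
#' @export
simulate_cohort <- function(cohort, n_trials = 4, sim_par = sim_params(),
                            seed = 1L) {
  stopifnot(length(cohort) >= 1, n_trials >= 1)
  trials <- vector("list", length(cohort) * n_trials)
  k <- 0L
  for (pi in seq_along(cohort)) {
    pilot_par <- cohort[[pi]]
    for (ti in seq_len(n_trials)) {
      k <- k + 1L
      trial_seed <- (as.integer(seed) * 10007L + pi * 131L + ti) %% 2147483647L
      pilot <- make_pilot(pilot_par, sim_par)
      tr <- simulate_trial(pilot, sim_par, seed = trial_seed)
      attr(tr, "pilot_id") <- pi
      attr(tr, "trial_id") <- ti
      trials[[k]] <- tr
    }
  }
  trials
}
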