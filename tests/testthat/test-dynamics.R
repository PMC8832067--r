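test_that("equilibrium is a fixed point and trajectories are odd-symmetric", {
  p <- sim_params()
  s <- mars_step(list(theta = 0, omega = 0), 0, p)
  expect_identical(c(s$theta, s$omega), c(0, 0))

  set.seed(1)
  for (i in 1:10) {
    th <- runif(1, -50, 50); om <- runif(1, -200, 200); u <- runif(1, -1, 1)
    a <- mars_step(list(theta = th, omega = om), u, p)
    b <- mars_step(list(theta = -th, omega = -om), -u, p)
    expect_equal(c(b$theta, b$omega), -c(a$theta, a$omega), tolerance = 1e-12)
  }
})

test_that("a single step matches the fine-step Euler oracle", {
  p <- sim_params()
  s <- mars_step(list(theta = 10, omega = 0), 0, p)
  expect_equal(s$theta, 10.021, tolerance = 1e-4)
  expect_equal(s$omega, 2.085, tolerance = 1e-3)
  o <- euler_oracle(10, 0, 0, p, t_end = p$dt, dt_fine = 1e-6)
  expect_equal(s$theta, o$theta, tolerance = 1e-6)
  expect_equal(s$omega, o$omega, tolerance = 1e-4)

  # with joystick coupling: velocity increment applied before integration
  s2 <- mars_step(list(theta = 5, omega = 20), -0.5, p)
  o2 <- euler_oracle(5, 20, -0.5, p, t_end = p$dt, dt_fine = 1e-6)
  expect_equal(s2$omega, o2$omega, tolerance = 1e-4)
})

test_that("the acceleration clamp engages inside the ODE right-hand side", {
  p <- sim_params()
  # 600*sin(30 deg) = 300 > 180: clamp active
  expect_equal(marsbalance:::pendulum_accel(30, p), 180)
  expect_equal(marsbalance:::pendulum_accel(-30, p), -180)
  # below the clamp threshold it is the raw pendulum term
  expect_equal(marsbalance:::pendulum_accel(10, p), 600 * sin(10 * pi / 180))
})

test_that("linearized natural frequency follows the square-root law", {
  expect_equal(round(natural_frequency(sim_params()), 2), 0.52)
  expect_equal(natural_frequency(sim_params()), 0.515, tolerance = 1e-3)
  f1 <- natural_frequency(sim_params(pendulum_constant = 600))
  f4 <- natural_frequency(sim_params(pendulum_constant = 2400))
  expect_equal(f4, 2 * f1, tolerance = 1e-12)
  kp_unit <- (180 / pi) * (2 * pi)^2
  expect_equal(natural_frequency(sim_params(pendulum_constant = kp_unit)), 1,
               tolerance = 1e-12)
})

test_that("RK4 converges at fourth order and tracks the Euler oracle", {
  run_rk4 <- function(dt, t_end = 1) {
    p <- sim_params(dt = dt, velocity_limit = 1e7, acceleration_limit = 1e7)
    th <- 5; om <- 0
    for (i in seq_len(round(t_end / dt))) {
      s <- mars_step(list(theta = th, omega = om), 0, p)
      th <- s$theta; om <- s$omega
    }
    th
  }
  ref <- run_rk4(0.00125)                 # near-exact fine RK4 reference
  err1 <- abs(run_rk4(0.02) - ref)
  err2 <- abs(run_rk4(0.01) - ref)
  expect_lt(err2, err1)
  expect_gt(err1 / err2, 10)              # ~16 for O(dt^4)
  expect_lt(err1 / err2, 24)

  p_free <- sim_params(velocity_limit = 1e7, acceleration_limit = 1e7)
  oracle <- euler_oracle(5, 0, 0, p_free, t_end = 1, dt_fine = 1e-5)
  expect_equal(run_rk4(0.02), oracle$theta, tolerance = 2e-3)
})

test_that("the energy-like invariant is conserved without clamps", {
  p <- sim_params(velocity_limit = 1e7, acceleration_limit = 1e7)
  energy <- function(th, om) {
    om^2 / 2 + p$pendulum_constant * (180 / pi) * cos(th * pi / 180)
  }
  th <- 10; om <- 0
  e0 <- energy(th, om)
  for (i in 1:50) {                       # 1 s at dt = 0.02
    s <- mars_step(list(theta = th, omega = om), 0, p)
    th <- s$theta; om <- s$omega
  }
  expect_lt(abs(energy(th, om) - e0) / abs(e0), 1e-6)
})

test_that("crash detection clips overshoot to the boundary", {
  p <- sim_params()
  expect_null(detect_crash(list(theta = 59.99, t = 1), p))
  cr <- detect_crash(list(theta = 60, t = 1), p)
  expect_equal(cr$theta, 60)
  cr2 <- detect_crash(list(theta = -60.3, t = 2), p)
  expect_equal(cr2$theta, -60)
})

test_that("non-finite state or joystick commands are rejected", {
  p <- sim_params()
  expect_error(mars_step(list(theta = NaN, omega = 0), 0, p), "non-finite")
  expect_error(mars_step(list(theta = 0, omega = 0), 2, p), "\\[-1, 1\\]")
})

test_that("an uncontrolled trial diverges monotonically into the + boundary", {
  p <- sim_params(trial_balance_seconds = 10)
  tr <- simulate_trial(function(h) 0, p, seed = 1, theta0 = 0.1)
  expect_gte(length(tr$crash_times), 1)
  upto <- which(tr$samples$t <= tr$crash_times[1])
  expect_true(all(diff(tr$samples$theta[upto]) >= 0))
  expect_equal(tr$samples$theta[max(upto)], 60)
})

test_that("resets run at the reset rate with the joystick disabled", {
  p <- sim_params(trial_balance_seconds = 10)
  tr <- simulate_trial(function(h) 0, p, seed = 1, theta0 = 0.1)
  s <- tr$samples
  r <- rle(s$control_enabled)
  reset_runs <- r$lengths[!r$values]
  # 60 deg at 5 deg/s = 12 s = 600 samples per full reset
  expect_true(all(abs(reset_runs - 600) <= 1))
  expect_true(all(s$joystick[!s$control_enabled] == 0))
})

test_that("trials are deterministic and respect balance-time bookkeeping", {
  p <- sim_params(trial_balance_seconds = 20)
  pilot1 <- make_pilot(pilot_params(), p)
  pilot2 <- make_pilot(pilot_params(), p)
  a <- simulate_trial(pilot1, p, seed = 7)
  b <- simulate_trial(pilot2, p, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$crash_times, b$crash_times)

  expect_equal(a$cumulative_balance_time, 20, tolerance = p$dt)
  # control_enabled samples: one per balancing step plus the initial sample
  expect_equal(sum(a$samples$control_enabled), 20 / p$dt + 1)
  expect_true(all(abs(a$samples$omega) <= p$velocity_limit))
  expect_true(all(abs(a$samples$theta) <= p$crash_boundary))
  expect_true(all(diff(a$samples$t) > 0))
  expect_equal(max(abs(diff(a$samples$t) - p$dt)), 0, tolerance = 1e-9)
})

test_that("out-of-range pilot commands are clipped with a warning", {
  p <- sim_params(trial_balance_seconds = 1)
  expect_warning(tr <- simulate_trial(function(h) 5, p, seed = 1),
                 "clipping")
  expect_true(all(tr$samples$joystick <= 1))
})
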