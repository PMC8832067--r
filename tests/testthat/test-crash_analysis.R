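test_that("position-binned misclassification rates keep their books", {
  st <- fixture_study()
  mis <- misclassification_by_position(st$predictions, st$threshold)
  expect_equal(nrow(mis), 6)
  expect_equal(sum(mis$n_crash) + sum(mis$n_noncrash),
               nrow(st$predictions))
  ok <- !is.na(mis$fn_rate)
  expect_true(all(mis$fn_rate[ok] >= 0 & mis$fn_rate[ok] <= 1))
  ok <- !is.na(mis$fp_rate)
  expect_true(all(mis$fp_rate[ok] >= 0 & mis$fp_rate[ok] <= 1))
})

test_that("a perfect classifier has zero misclassification everywhere", {
  pr <- data.frame(score = c(0.9, 0.9, 0.1, 0.1),
                   label = c(1, 1, 0, 0),
                   max_abs_theta = c(5, 55, 15, 45))
  mis <- misclassification_by_position(pr, 0.5)
  expect_true(all(mis$fn_rate[!is.na(mis$fn_rate)] == 0))
  expect_true(all(mis$fp_rate[!is.na(mis$fp_rate)] == 0))
})

test_that("missed crashes concentrate near the balance point", {
  # crashes whose window never strays far from 0 deg are the ones whose
  # cause (a destabilizing deflection after the window) the model cannot
  # see, so they score lower and dominate the misses at 95% recall
  st <- fixture_gru_800()
  crash <- st$predictions[st$predictions$label == 1, ]
  low <- crash$max_abs_theta < 30
  expect_gt(sum(low), 20)
  expect_lt(mean(crash$score[low]), mean(crash$score[!low]))

  mis <- misclassification_by_position(st$predictions, st$threshold,
                                       bin_edges = c(0, 20, 40, 60))
  expect_equal(which.max(mis$fn_rate), 1L)
  expect_true(all(diff(mis$fn_rate) <= 0))
})

test_that("an ideal pilot produces no destabilizing deflections anywhere", {
  pp <- pilot_params(position_leak = 0, estimate_noise_sd = 0,
                     reaction_delay = 0, sign_error_prob = 0,
                     deflection_rate_hz = 25, prediction = 0)
  p <- sim_params(trial_balance_seconds = 30)
  tr <- simulate_trial(make_pilot(pp, p), p, seed = 5, theta0 = 1)
  s <- tr$samples
  expect_equal(sum(djd_flag(s$theta, s$omega, s$joystick)), 0)
  eps <- extract_episodes(tr)
  ws <- suppressMessages(make_window_set(eps, 1000, 800, 10))
  pr <- predict(build_model(model_spec("LINEAR", seed = 1), 50, 4), ws)
  rates <- djd_rate_by_prediction_type(pr, list(tr), 800, 0.5)
  expect_true(all(rates$djd_rate[!is.na(rates$djd_rate)] == 0))
})

test_that("destabilizing deflections in the look-ahead mark the missed crashes", {
  st <- fixture_study()
  rates <- djd_rate_by_prediction_type(st$predictions, st$trials, 800,
                                       st$threshold)
  expect_setequal(rates$type, c("FN", "FP", "TN", "TP"))
  r <- setNames(rates$djd_rate, rates$type)
  expect_true(all(r[!is.na(r)] >= 0 & r[!is.na(r)] <= 1))
  expect_gt(r["FN"], r["TP"])
  # fractional variant is bounded by the any-step variant
  fr <- djd_rate_by_prediction_type(st$predictions, st$trials, 800,
                                    st$threshold, how = "fraction")
  expect_true(all(fr$djd_rate <= r[fr$type] + 1e-12, na.rm = TRUE))
})

test_that("state densities are normalized, bounded, and rank danger correctly", {
  st <- fixture_study()
  dens <- state_density_by_type(st$predictions, st$trials, 800, st$threshold)
  for (tp in c("FN", "FP", "TN", "TP")) {
    m <- dens[[tp]]
    if (all(is.na(m))) next
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  # mean |position| under false-positive mass exceeds true-negative mass
  th_mid <- (dens$breaks$theta[-1] + dens$breaks$theta[-25]) / 2
  mean_abs_theta <- function(m) sum(rowSums(m) * abs(th_mid))
  expect_gt(mean_abs_theta(dens$FP), mean_abs_theta(dens$TN))
})

test_that("the recoverable region has the required geometry", {
  p <- sim_params()
  reg <- compute_recoverable_region(p, theta_step = 4, omega_step = 20,
                                    horizon = 8)
  expect_true(is_recoverable(reg, 0, 0))
  expect_false(any(is_recoverable(reg, c(60, -60, 60), c(0, 100, -250))))
  expect_false(is_recoverable(reg, 59, 200))
  # symmetry under (theta, omega) -> (-theta, -omega)
  expect_equal(reg$recoverable,
               reg$recoverable[rev(seq_along(reg$theta)),
                               rev(seq_along(reg$omega))])
  # nestedness in control authority
  reg_weak <- compute_recoverable_region(sim_params(joystick_gain = 3),
                                         theta_step = 4, omega_step = 20,
                                         horizon = 8)
  expect_true(all(reg$recoverable[reg_weak$recoverable]))
  expect_gt(sum(reg$recoverable), sum(reg_weak$recoverable))
})

test_that("no random policy rescues a state the extremal policy loses", {
  p <- sim_params()
  reg <- compute_recoverable_region(p, theta_step = 4, omega_step = 20,
                                    horizon = 8)
  set.seed(33)
  # sample unrecoverable, not-yet-crashed states
  idx <- which(!reg$recoverable, arr.ind = TRUE)
  idx <- idx[abs(reg$theta[idx[, 1]]) < p$crash_boundary, , drop = FALSE]
  idx <- idx[sample(nrow(idx), 50), , drop = FALSE]
  n_steps <- round(8 / p$dt)
  for (k in seq_len(nrow(idx))) {
    th0 <- reg$theta[idx[k, 1]]; om0 <- reg$omega[idx[k, 2]]
    # 30 random piecewise-constant policies, resampled every ~0.2 s
    th <- rep(th0, 30); om <- rep(om0, 30)
    alive <- rep(TRUE, 30)
    u <- runif(30, -1, 1)
    for (s in seq_len(n_steps)) {
      if (!any(alive)) break
      if (s %% 10 == 0) u[alive] <- runif(sum(alive), -1, 1)
      st <- marsbalance:::vec_step(th[alive], om[alive], u[alive], p)
      crashed <- abs(st$theta) >= p$crash_boundary
      th[alive] <- st$theta; om[alive] <- st$omega
      alive[alive] <- !crashed
    }
    expect_false(any(alive),
                 label = sprintf("state (%g, %g) saved by a random policy",
                                 th0, om0))
  }
})

test_that("crash states walk back from the boundary along the episode", {
  trials <- fixture_trials()
  cs0 <- crash_states(trials, 0)
  expect_true(all(abs(cs0$theta) == 60))
  cs8 <- crash_states(trials, 0.8)
  expect_equal(nrow(cs8), nrow(cs0))
  # most crash episodes are longer than 800 ms, so the state is sampled at
  # or before crash_time - 0.8 s; short episodes fall back to their start
  lag <- cs8$crash_time - cs8$t
  expect_gt(mean(lag >= 0.8 - 1e-9), 0.8)
  expect_true(all(lag >= 0))
  expect_lt(mean(abs(cs8$theta)), mean(abs(cs0$theta)))
})

test_that("savability declines to exactly zero as the margin elapses", {
  trials <- fixture_trials()
  reg <- compute_recoverable_region(sim_params(), theta_step = 2,
                                    omega_step = 10)
  sav <- savable_fraction(trials, reg, c(0, 200, 400, 600, 800), 800)
  expect_equal(sav$pct_savable[sav$elapsed_ms == 800], 0)
  expect_true(all(diff(sav$pct_savable) <= 1e-9))
  expect_true(all(sav$pct_savable >= 0 & sav$pct_savable <= 100))
  # deterministic given the same inputs
  sav2 <- savable_fraction(trials, reg, c(0, 200, 400, 600, 800), 800)
  expect_identical(sav, sav2)
  expect_error(savable_fraction(trials, reg, 900, 800), "elapsed")
})
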