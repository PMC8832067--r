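test_that("episodes are the maximal crash/reset-delimited control runs", {
  # control(100) reset(50) control(80) reset(50) control(70): 2 crashes
  tr <- toy_trial(c(100, 50, 80, 50, 70), crash_after_run = c(TRUE, TRUE, FALSE))
  eps <- extract_episodes(tr)
  expect_length(eps, 3)
  expect_equal(sapply(eps, `[[`, "end_cause"),
               c("CRASH", "CRASH", "TRIAL_END"))
  expect_equal(sapply(eps, function(e) nrow(e$samples)), c(100, 80, 70))
  # time_to_crash decreases to 0 at the crash, Inf for the last episode
  expect_equal(eps[[1]]$time_to_crash[100], 0)
  expect_true(all(diff(eps[[1]]$time_to_crash) < 0))
  expect_true(all(is.infinite(eps[[3]]$time_to_crash)))

  tr0 <- toy_trial(c(120), crash_after_run = FALSE)
  eps0 <- extract_episodes(tr0)
  expect_length(eps0, 1)
  expect_equal(eps0[[1]]$end_cause, "TRIAL_END")
})

test_that("episode samples conserve the trial's balancing time", {
  p <- sim_params(trial_balance_seconds = 30)
  tr <- simulate_trial(make_pilot(pilot_params(), p), p, seed = 3)
  eps <- extract_episodes(tr)
  total <- sum(sapply(eps, function(e) nrow(e$samples)))
  # one sample per balancing step plus the initial sample
  expect_equal(total * p$dt, 30 + p$dt, tolerance = p$dt)
  # no sample of any episode is under automatic control
  expect_true(all(sapply(eps, function(e) all(e$samples$control_enabled))))
})

test_that("the destabilizing flag matches the 27-case sign enumeration", {
  vals <- c(-1.5, 0, 2.5)
  for (a in vals) for (b in vals) for (c in vals) {
    expected <- as.integer(sign(a) != 0 && sign(a) == sign(b) &&
                             sign(b) == sign(c))
    expect_identical(djd_flag(a, b, c), expected)
  }
  expect_identical(djd_flag(5, 10, 0.3), 1L)
  expect_identical(djd_flag(5, 10, -0.3), 0L)
  expect_identical(djd_flag(0, 10, 0.3), 0L)
})

test_that("window counts follow the stride formula and labels the advance rule", {
  # 3.00-s crash episode at dt = 0.02: 150 samples (t = 0 .. 2.98), L = 50
  tr <- toy_trial(c(150), crash_after_run = TRUE)
  ep <- extract_episodes(tr)[[1]]
  ws <- make_windows(ep, window_ms = 1000, advance_ms = 800, stride_steps = 1)
  expect_equal(length(ws$y), 101)
  expect_equal(ws$meta$end_time[1], 0.98)
  expect_equal(ws$meta$end_time[101], 2.98)
  # half-open (end, end + advance]: crash at 2.98 labels ends 2.18 .. 2.96,
  # 40 windows; the window ending at the crash instant itself is excluded
  expect_equal(sum(ws$y), 40)
  expect_equal(range(ws$meta$end_time[ws$y == 1]), c(2.18, 2.96))
  expect_equal(ws$y[101], 0L)          # window ending at the crash instant

  # advance 0: empty look-ahead interval
  ws0 <- make_windows(ep, 1000, 0, 1)
  expect_true(all(ws0$y == 0))

  # monotone in the advance duration
  n300 <- sum(make_windows(ep, 1000, 300, 1)$y)
  n1000 <- sum(make_windows(ep, 1000, 1000, 1)$y)
  expect_lte(n300, sum(ws$y))
  expect_lte(sum(ws$y), n1000)

  # count formula across strides
  for (st in c(1, 3, 7)) {
    wss <- make_windows(ep, 1000, 800, st)
    expect_equal(length(wss$y), floor((150 - 50) / st) + 1)
  }

  # shorter than the window: empty result
  short <- extract_episodes(toy_trial(c(30), crash_after_run = TRUE))[[1]]
  expect_message(wse <- make_windows(short, 1000, 800, 1), "shorter")
  expect_length(wse$y, 0)
})

test_that("labels agree with a brute-force crash scan on simulated trials", {
  p <- sim_params(trial_balance_seconds = 40)
  tr <- simulate_trial(make_pilot(pilot_params(), p), p, seed = 17)
  eps <- extract_episodes(tr)
  ws <- suppressMessages(make_window_set(eps, 1000, 800, 3))
  expect_gt(length(ws$y), 100)
  expect_equal(ws$y, brute_labels(ws$meta$end_time, tr$crash_times, 0.8))
  # no window touches a control-disabled sample
  for (i in seq_len(nrow(ws$meta))) {
    lo <- ws$meta$end_index[i] - dim(ws$X)[2] + 1L
    expect_true(all(tr$samples$control_enabled[lo:ws$meta$end_index[i]]))
  }
  # channel 4 equals the flag recomputed from channels 1-3
  recomputed <- djd_flag(c(ws$X[, , 1]), c(ws$X[, , 2]), c(ws$X[, , 3]))
  expect_equal(c(ws$X[, , 4]), as.numeric(recomputed))
})

test_that("episode splits hit the exact floor arithmetic", {
  sp <- split_episodes(sprintf("e%05d", 1:21469), 0.9, seed = 1)
  expect_equal(sum(sp$split == "TRAIN"), 19322)
  expect_equal(sum(sp$split == "TEST"), 2147)

  sp10 <- split_episodes(sprintf("e%d", 1:10), 0.9, seed = 1)
  expect_equal(sum(sp10$split == "TRAIN"), 9)

  expect_identical(split_episodes(sprintf("e%d", 1:50), 0.8, seed = 4),
                   split_episodes(sprintf("e%d", 1:50), 0.8, seed = 4))
  expect_error(split_episodes(character(0), 0.9), "no episodes")
  expect_error(split_episodes(sprintf("e%d", 1:5), 1.2), "train_fraction")
})

test_that("fold assignment partitions episodes evenly", {
  fo <- assign_folds(sprintf("e%02d", 1:20), k = 10, seed = 2)
  expect_equal(as.integer(table(fo$fold)), rep(2L, 10))
  fo23 <- assign_folds(sprintf("e%02d", 1:23), k = 10, seed = 2)
  expect_lte(diff(range(table(fo23$fold))), 1)
  expect_setequal(fo23$episode_id, sprintf("e%02d", 1:23))
  expect_error(assign_folds(sprintf("e%d", 1:5), k = 10), "fewer episodes")
  expect_error(assign_folds(sprintf("e%d", 1:5), k = 1), "k must be")
})

test_that("every window of an episode shares its episode's fold", {
  ws <- fixture_windows()
  ids <- unique(ws$meta$episode_id)
  fo <- assign_folds(ids, k = 5, seed = 9)
  fold_of <- fo$fold[match(ws$meta$episode_id, fo$episode_id)]
  per_ep <- tapply(fold_of, ws$meta$episode_id, function(f)
    length(unique(f)))
  expect_true(all(per_ep == 1))
})

test_that("standardization uses training statistics and is invertible", {
  ws <- fixture_windows()
  st <- channel_stats(ws)
  zs <- standardize_windows(ws, st)
  expect_equal(mean(zs$X[, , 1]), 0, tolerance = 1e-10)
  expect_equal(sd(c(zs$X[, , 2])), 1, tolerance = 1e-10)
  back <- zs
  for (c in 1:4) back$X[, , c] <- back$X[, , c] * st$sd[c] + st$mean[c]
  expect_equal(back$X, ws$X, tolerance = 1e-10)
})
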