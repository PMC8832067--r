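# Independent oracles, kept deliberately naive: fine-step explicit Euler for
# the device ODE, O(P*N) pair counting for AUC, exhaustive threshold sweeps
# for precision-at-recall.  None of them shares code with the implementation
# paths they check.

# Fine-step explicit Euler on the clamped pendulum ODE.  The joystick
# increment (gain * u) is applied once, up front, mirroring one device step.
euler_oracle <- function(theta, omega, u = 0, params = sim_params(),
                         t_end = params$dt, dt_fine = 1e-5) {
  omega <- omega + params$joystick_gain * u
  n <- round(t_end / dt_fine)
  for (i in seq_len(n)) {
    a <- params$pendulum_constant * sin(theta * pi / 180)
    a <- max(-params$acceleration_limit, min(params$acceleration_limit, a))
    theta <- theta + omega * dt_fine
    omega <- omega + a * dt_fine
    omega <- max(-params$velocity_limit, min(params$velocity_limit, omega))
  }
  list(theta = theta, omega = omega)
}

# AUC by explicit enumeration of positive-negative pairs (ties = 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Precision at recall by exhaustive sweep over every distinct score cut:
# among cuts (score >= cut) achieving recall >= target, the one with maximal
# precision, ties broken toward the larger cut.
brute_precision_at_recall <- function(scores, labels, target) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (cut in cuts) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1)
    rec <- tp / sum(labels == 1)
    if (rec >= target) {
      prec <- tp / sum(pred)
      if (is.null(best) || prec > best$precision) {
        best <- list(precision = prec, threshold = cut)
      }
    }
  }
  best
}

# Brute-force window labeling: scan all crash times of the trial.
brute_labels <- function(end_times, crash_times, advance_s) {
  vapply(end_times, function(e)
    as.integer(any(crash_times > e & crash_times <= e + advance_s)),
    integer(1))
}

# A hand-built trial record (uniform sampling, explicit reset runs).
toy_trial <- function(control_runs, crash_after_run, dt = 0.02, seed = 99L) {
  # control_runs: lengths of alternating control/reset runs starting with
  # control; crash_after_run: logical per control run (ends in crash?)
  t <- numeric(0); ce <- logical(0)
  for (i in seq_along(control_runs)) {
    ce <- c(ce, rep(i %% 2 == 1, control_runs[i]))
  }
  n <- length(ce)
  t <- seq(0, by = dt, length.out = n)
  theta <- rep(0, n); theta[!ce] <- 30
  samples <- data.frame(t = t, theta = theta, omega = 0, joystick = 0,
                        control_enabled = ce)
  # crash time = last sample of each crashing control run
  ends <- cumsum(control_runs)
  ctrl_idx <- which(seq_along(control_runs) %% 2 == 1)
  crash_times <- t[ends[ctrl_idx][crash_after_run]]
  structure(list(samples = samples, crash_times = crash_times,
                 cumulative_balance_time = sum(ce) * dt,
                 params = sim_params(dt = dt), seed = seed),
            class = "trial_record")
}

# A window set of pure-noise features with alternating labels.
rand_ws <- function(N, L = 10L, C = 4L, seed = 1, ids = NULL) {
  set.seed(seed)
  X <- array(rnorm(N * L * C), dim = c(N, L, C))
  y <- rep_len(c(1L, 0L), N)
  if (is.null(ids)) ids <- paste0("e", seq_len(N))
  structure(list(
    X = X, y = y,
    meta = data.frame(episode_id = ids, trial_key = "t",
                      end_time = seq_len(N) * 0.02,
                      end_index = seq_len(N), max_abs_theta = 0,
                      time_to_crash = Inf),
    window_ms = L * 20, advance_ms = 800, stride_steps = 1L, dt = 0.02),
    class = "window_set")
}

# Small simulated fixtures, memoised per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture_trials <- function() {
  if (is.null(.fixture_env$trials)) {
    cohort <- make_cohort(5, difficulty = c(0.3, 0.9), seed = 21)
    .fixture_env$trials <- simulate_cohort(cohort, 2,
                                           sim_params(trial_balance_seconds = 50),
                                           seed = 22)
  }
  .fixture_env$trials
}

fixture_windows <- function() {
  if (is.null(.fixture_env$ws)) {
    eps <- unlist(lapply(fixture_trials(), extract_episodes),
                  recursive = FALSE)
    .fixture_env$ws <- suppressMessages(
      make_window_set(eps, 1000, 800, stride_steps = 10))
  }
  .fixture_env$ws
}

# The package's scaled study conditions: a default-difficulty cohort of 10
# pilots x 4 full-length trials.  Simulated once and shared by the
# end-to-end and crash-analysis tests.
fixture_e2e <- function() {
  if (is.null(.fixture_env$e2e)) {
    cohort <- make_cohort(10, seed = 1)
    trials <- simulate_cohort(cohort, n_trials = 4, sim_params(), seed = 1)
    episodes <- unlist(lapply(trials, extract_episodes), recursive = FALSE)
    .fixture_env$e2e <- list(trials = trials, episodes = episodes)
  }
  .fixture_env$e2e
}

# A stacked GRU trained at the headline 1,000 ms / 800 ms configuration on
# the study-condition cohort, with held-out predictions and the threshold
# at 95% recall.
fixture_gru_800 <- function() {
  if (is.null(.fixture_env$gru800)) {
    eps <- fixture_e2e()$episodes
    ws <- suppressMessages(make_window_set(eps, 1000, 800, 20))
    sp <- split_episodes(unique(ws$meta$episode_id), 0.8, seed = 61)
    tr <- ws[ws$meta$episode_id %in% sp$episode_id[sp$split == "TRAIN"]]
    te <- ws[ws$meta$episode_id %in% sp$episode_id[sp$split == "TEST"]]
    st <- channel_stats(tr)
    m <- build_model(model_spec("STACKED_GRU", hidden = 32, head_width = 32,
                                lr = 3e-3, lr_decay = 0.93, max_epochs = 8,
                                seed = 62), 50, 4)
    m <- train_model(m, standardize_windows(tr, st))
    preds <- predict(m, standardize_windows(te, st))
    pa <- precision_at_recall(preds, 0.95)
    .fixture_env$gru800 <- list(model = m, predictions = preds,
                                threshold = pa$threshold,
                                precision = pa$precision)
  }
  .fixture_env$gru800
}

# A quick trained model + held-out predictions over the fixture cohort,
# shared by the evaluation and crash-analysis tests.
fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    ws <- fixture_windows()
    sp <- split_episodes(unique(ws$meta$episode_id), 0.8, seed = 23)
    tr <- ws[ws$meta$episode_id %in% sp$episode_id[sp$split == "TRAIN"]]
    te <- ws[ws$meta$episode_id %in% sp$episode_id[sp$split == "TEST"]]
    st <- channel_stats(tr)
    m <- build_model(scaled_spec("MLP", max_epochs = 12, seed = 24), 50, 4)
    m <- train_model(m, standardize_windows(tr, st))
    preds <- predict(m, standardize_windows(te, st))
    pa <- precision_at_recall(preds, 0.95)
    .fixture_env$study <- list(model = m, predictions = preds,
                               threshold = pa$threshold,
                               trials = fixture_trials())
  }
  .fixture_env$study
}
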