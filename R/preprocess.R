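# Episode extraction and sliding-window sample construction.
#
# An episode is a maximal contiguous run of human-controlled, crash-free
# samples; crashes and automatic resets delimit episodes.  Windows never
# cross episode boundaries, so no window overlaps a reset, and splits are
# made at the episode level to prevent leakage between training and testing.

#' Extract episodes from a trial
#'
#' Episodes are the maximal runs of `control_enabled` samples.  A run whose
#' last sample coincides with a crash gets `end_cause = "CRASH"`; the run
#' reaching the end of the trial gets `end_cause = "TRIAL_END"`.
#'
#' @param trial a `trial_record` from [simulate_trial()] or
#'   [read_trial_csv()].
#' @return A list of `episode` objects: lists with `trial_seed`, `start`,
#'   `end` (half-open 0-based sample range into the trial), `samples`
#'   (data.frame slice), `end_cause`, `crash_time` (NA for TRIAL_END) and
#'   `time_to_crash` (s per sample, `Inf` for TRIAL_END episodes).
#' @examples
#' tr <- simulate_trial(function(h) 0, sim_params(trial_balance_seconds = 5),
#'                      seed = 1, theta0 = 0.1)
#' length(extract_episodes(tr))
#' @export
extract_episodes <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$samples
  dt <- trial$params$dt
  r <- rle(s$control_enabled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i0 <- starts[keep[k]]; i1 <- ends[keep[k]]
    seg <- s[i0:i1, , drop = FALSE]
    last_t <- seg$t[nrow(seg)]
    is_crash <- any(abs(trial$crash_times - last_t) < dt / 2)
    out[[k]] <- structure(list(
      trial_seed = trial$seed,
      pilot_id = attr(trial, "pilot_id"),
      trial_id = attr(trial, "trial_id"),
      start = i0 - 1L,
      end = i1,
      samples = seg,
      end_cause = if (is_crash) "CRASH" else "TRIAL_END",
      crash_time = if (is_crash) last_t else NA_real_,
      time_to_crash = if (is_crash) last_t - seg$t else rep(Inf, nrow(seg)),
      dt = dt
    ), class = "episode")
  }
  out
}

#' Destabilizing joystick deflection flag
#'
#' A time step is destabilizing when angular position, angular velocity and
#' joystick deflection all share the same sign: the commanded torque then
#' accelerates the device toward the crash boundary it is already moving
#' toward.  A zero in any channel carries no sign and breaks the condition.
#'
#' @param theta angular position, deg (vectorized).
#' @param omega angular velocity, deg/s.
#' @param joystick joystick deflection in \[-1, 1\].
#' @return Integer vector of 0/1 flags.
#' @examples
#' djd_flag(5, 10, 0.3)    # 1
#' djd_flag(5, 10, -0.3)   # 0
#' djd_flag(0, 10, 0.3)    # 0: zero position has no sign
#' @export
djd_flag <- function(theta, omega, joystick) {
  stopifnot(all(is.finite(theta)), all(is.finite(omega)),
            all(is.finite(joystick)))
  s1 <- sign(theta); s2 <- sign(omega); s3 <- sign(joystick)
  as.integer(s1 != 0 & s1 == s2 & s2 == s3)
}

#' Cut an episode into labeled sliding windows
#'
#' Slides a window of `window_ms` across the episode in steps of
#' `stride_steps` samples.  Each window's feature block is an L x 4 matrix
#' (position deg, velocity deg/s, joystick, destabilizing-deflection flag),
#' with `L = round(window_ms / (dt * 1000))`.  The label is 1 iff the
#' episode ends in a crash that falls in the half-open look-ahead interval
#' `(end_time, end_time + advance_ms]` after the window; windows of
#' TRIAL_END episodes are all labeled 0.  Windows never extend outside the
#' episode, hence never overlap reset periods.
#'
#' @param episode an `episode` from [extract_episodes()].
#' @param window_ms window length, ms (default 1000).
#' @param advance_ms look-ahead ("time-in-advance") used for labeling, ms
#'   (default 800).
#' @param stride_steps slide step in samples (default 1, i.e. 20 ms).
#' @return A `window_set`: list with `X` (N x L x 4 array), `y` (integer
#'   0/1), and `meta` (data.frame: `episode_id`, `end_time` s, `end_index`
#'   0-based exclusive index into the trial, `max_abs_theta` deg,
#'   `time_to_crash` s).  N = 0 (with a message) if the episode is shorter
#'   than the window.
#' @export
make_windows <- function(episode, window_ms = 1000, advance_ms = 800,
                         stride_steps = 1L) {
  stopifnot(inherits(episode, "episode"), window_ms > 0, advance_ms >= 0,
            stride_steps >= 1)
  dt <- episode$dt
  L <- as.integer(round(window_ms / (dt * 1000)))
  seg <- episode$samples
  n <- nrow(seg)
  ep_id <- episode_id(episode)
  if (n < L) {
    message("episode ", ep_id, " shorter than window (", n, " < ", L,
            " samples); no windows")
    return(empty_window_set(L))
  }
  starts <- seq.int(1L, n - L + 1L, by = stride_steps)
  ends <- starts + L - 1L
  end_time <- seg$t[ends]
  ttc <- episode$time_to_crash[ends]           # Inf for TRIAL_END
  y <- as.integer(is.finite(ttc) & ttc > 0 & ttc <= advance_ms / 1000)
  djd <- djd_flag(seg$theta, seg$omega, seg$joystick)
  idx <- outer(starts, 0:(L - 1L), `+`)        # N x L sample indices
  X <- array(NA_real_, dim = c(length(starts), L, 4L),
             dimnames = list(NULL, NULL,
                             c("theta", "omega", "joystick", "djd")))
  X[, , 1] <- seg$theta[idx]
  X[, , 2] <- seg$omega[idx]
  X[, , 3] <- seg$joystick[idx]
  X[, , 4] <- djd[idx]
  abs_th <- matrix(abs(seg$theta[idx]), nrow = length(starts))
  meta <- data.frame(
    episode_id = rep(ep_id, length(starts)),
    trial_key = rep(trial_key_of(episode), length(starts)),
    end_time = end_time,
    end_index = episode$start + ends,          # 0-based exclusive
    max_abs_theta = apply(abs_th, 1, max),
    time_to_crash = ttc,
    stringsAsFactors = FALSE
  )
  structure(list(X = X, y = y, meta = meta,
                 window_ms = window_ms, advance_ms = advance_ms,
                 stride_steps = as.integer(stride_steps), dt = dt),
            class = "window_set")
}

episode_id <- function(episode) {
  paste0(trial_key_of(episode), "e", episode$start)
}

trial_key_of <- function(x) {
  if (inherits(x, "trial_record")) {
    paste0("s", x$seed,
           if (!is.null(attr(x, "pilot_id"))) paste0("p", attr(x, "pilot_id")),
           if (!is.null(attr(x, "trial_id"))) paste0("t", attr(x, "trial_id")))
  } else {
    paste0("s", x$trial_seed,
           if (!is.null(x$pilot_id)) paste0("p", x$pilot_id),
           if (!is.null(x$trial_id)) paste0("t", x$trial_id))
  }
}

empty_window_set <- function(L) {
  structure(list(
    X = array(numeric(0), dim = c(0L, L, 4L)),
    y = integer(0),
    meta = data.frame(episode_id = character(0), trial_key = character(0),
                      end_time = numeric(0),
                      end_index = integer(0), max_abs_theta = numeric(0),
                      time_to_crash = numeric(0)),
    window_ms = NA_real_, advance_ms = NA_real_, stride_steps = 1L,
    dt = NA_real_), class = "window_set")
}

#' Build a window set from many episodes
#'
#' Applies [make_windows()] to each episode and concatenates the results.
#'
#' @param episodes list of `episode` objects.
#' @inheritParams make_windows
#' @return A `window_set` (see [make_windows()]).
#' @export
make_window_set <- function(episodes, window_ms = 1000, advance_ms = 800,
                            stride_steps = 1L) {
  parts <- lapply(episodes, function(e) suppressMessages(
    make_windows(e, window_ms = window_ms, advance_ms = advance_ms,
                 stride_steps = stride_steps)))
  n_short <- sum(vapply(parts, function(p) length(p$y) == 0, logical(1)))
  if (n_short > 0) {
    message(n_short, " of ", length(episodes),
            " episodes shorter than the window; skipped")
  }
  parts <- Filter(function(p) length(p$y) > 0, parts)
  if (length(parts) == 0) {
    L <- as.integer(round(window_ms / (episodes[[1]]$dt * 1000)))
    return(empty_window_set(L))
  }
  X <- do.call(abind1, lapply(parts, `[[`, "X"))
  structure(list(
    X = X,
    y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
    meta = do.call(rbind, lapply(parts, `[[`, "meta")),
    window_ms = window_ms, advance_ms = advance_ms,
    stride_steps = as.integer(stride_steps), dt = parts[[1]]$dt),
    class = "window_set")
}

# rbind for 3-d arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[-1]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "window_set: %d windows of %d steps x %d channels (%g ms window, %g ms advance)\n",
    dim(x$X)[1], dim(x$X)[2], dim(x$X)[3], x$window_ms, x$advance_ms))
  cat(sprintf("  crash-labeled: %d (%.1f%%), episodes: %d\n",
              sum(x$y), 100 * mean(x$y),
              length(unique(x$meta$episode_id))))
  invisible(x)
}

#' Subset a window set
#' @param x a `window_set`.
#' @param i integer or logical index over windows.
#' @param ... unused.
#' @return A `window_set` with the selected windows.
#' @export
`[.window_set` <- function(x, i, ...) {
  structure(list(X = x$X[i, , , drop = FALSE], y = x$y[i],
                 meta = x$meta[i, , drop = FALSE],
                 window_ms = x$window_ms, advance_ms = x$advance_ms,
                 stride_steps = x$stride_steps, dt = x$dt),
            class = "window_set")
}

#' Split episodes into training and test pools
#'
#' Uniformly random episode-level split: all windows of an episode land on
#' the same side, preventing leakage of near-duplicate windows across the
#' train/test boundary.  The training pool receives
#' `floor(train_fraction * N)` episodes.
#'
#' @param episodes list of `episode` objects (or their ids).
#' @param train_fraction fraction of episodes assigned to training,
#'   in (0, 1) (default 0.9).
#' @param seed integer seed.
#' @return A data.frame with `episode_id` and `split` ("TRAIN"/"TEST").
#' @examples
#' # 21,469 episodes at 90% -> 19,322 train / 2,147 test
#' sp <- split_episodes(sprintf("e%05d", 1:21469), 0.9, seed = 1)
#' table(sp$split)
#' @export
split_episodes <- function(episodes, train_fraction = 0.9, seed = 1L) {
  ids <- episode_ids(episodes)
  n <- length(ids)
  if (n == 0) stop("no episodes to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  set.seed(as.integer(seed))
  n_train <- floor(train_fraction * n)
  train_idx <- sample.int(n, n_train)
  split <- rep("TEST", n)
  split[train_idx] <- "TRAIN"
  data.frame(episode_id = ids, split = split, stringsAsFactors = FALSE)
}

#' Assign training episodes to cross-validation folds
#'
#' Episode-level partition into `k` folds of sizes differing by at most one
#' episode; every window of an episode shares its episode's fold.
#'
#' @param episodes list of `episode` objects (or their ids).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return A data.frame with `episode_id` and `fold` (0-based fold index).
#' @export
assign_folds <- function(episodes, k = 10L, seed = 1L) {
  ids <- episode_ids(episodes)
  n <- length(ids)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer episodes (", n, ") than folds (", k, ")")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- (seq_len(n) - 1L) %% as.integer(k)
  data.frame(episode_id = ids, fold = fold, stringsAsFactors = FALSE)
}

episode_ids <- function(episodes) {
  if (is.character(episodes)) return(episodes)
  ids <- vapply(episodes, function(e) {
    if (inherits(e, "episode")) episode_id(e) else as.character(e)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate episode ids")
  ids
}

#' Channel standardization statistics from a training pool
#'
#' Computes per-channel mean and standard deviation over all time steps of
#' the supplied (training) windows.  Apply with [standardize_windows()].
#' Raw channels live on very different scales (degrees, deg/s, unit
#' deflection, 0/1 flag), so inputs are z-scored before training; the
#' statistics must come from the training split only.
#'
#' @param ws a `window_set` (training pool).
#' @return A list with numeric vectors `mean` and `sd` (length 4).
#' @export
channel_stats <- function(ws) {
  stopifnot(inherits(ws, "window_set"), dim(ws$X)[1] > 0)
  m <- apply(ws$X, 3, mean)
  s <- apply(ws$X, 3, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, sd = s)
}

#' Apply channel standardization
#' @param ws a `window_set`.
#' @param stats a list from [channel_stats()].
#' @return The `window_set` with z-scored channels.
#' @export
standardize_windows <- function(ws, stats) {
  for (c in seq_len(dim(ws$X)[3])) {
    ws$X[, , c] <- (ws$X[, , c] - stats$mean[c]) / stats$sd[c]
  }
  ws
}
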