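# Canonical on-disk formats: trials as CSV with a JSON sidecar, window
# sets via R serialization, configs as YAML.

#' Write a trial to CSV (+ JSON sidecar)
#'
#' Samples go to `<path>` with header `t,theta,omega,joystick,
#' control_enabled`; crash times, seed and simulation parameters go to
#' `<path>.json`.
#'
#' @param trial a `trial_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$samples
  s$control_enabled <- as.integer(s$control_enabled)
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    crashes = trial$crash_times,
    seed = trial$seed,
    cumulative_balance_time = trial$cumulative_balance_time,
    params = unclass(trial$params),
    pilot_id = attr(trial, "pilot_id"),
    trial_id = attr(trial, "trial_id")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial from CSV (+ JSON sidecar)
#'
#' Validates the canonical schema: required columns, strictly increasing
#' uniformly spaced time, finite values, joystick within \[-1, 1\], and
#' positions within the crash boundary.
#'
#' @param path CSV path written by [write_trial_csv()].
#' @return A `trial_record`.
#' @export
read_trial_csv <- function(path) {
  s <- utils::read.csv(path)
  need <- c("t", "theta", "omega", "joystick", "control_enabled")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(s[need]) || !all(vapply(s[need[1:4]], function(x)
    all(is.finite(x)), logical(1)))) {
    stop("non-finite or missing values in trial samples")
  }
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("sidecar not found: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  params <- do.call(sim_params, as.list(side$params))
  dts <- diff(s$t)
  if (any(dts <= 0)) stop("time not strictly increasing")
  if (any(abs(dts - params$dt) > params$dt / 100)) {
    stop("non-uniform timestep: expected ", params$dt)
  }
  if (any(s$joystick < -1 | s$joystick > 1)) {
    stop("joystick deflections outside [-1, 1]")
  }
  if (any(abs(s$theta) > params$crash_boundary + 1e-9)) {
    stop("positions beyond the crash boundary")
  }
  s$control_enabled <- as.logical(s$control_enabled)
  tr <- structure(list(
    samples = s,
    crash_times = as.numeric(side$crashes %||% numeric(0)),
    cumulative_balance_time = side$cumulative_balance_time,
    params = params,
    seed = as.integer(side$seed)
  ), class = "trial_record")
  if (!is.null(side$pilot_id)) attr(tr, "pilot_id") <- side$pilot_id
  if (!is.null(side$trial_id)) attr(tr, "trial_id") <- side$trial_id
  tr
}

#' Persist / load a window set
#'
#' Window tensors are stored with R's native serialization; the arrays are
#' rebuilt from trials by [make_window_set()] whenever formats must be
#' exchanged instead.
#'
#' @param ws a `window_set`.
#' @param path file path (conventionally `windows.rds`).
#' @return `path` / the `window_set`.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(ws, path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  ws <- readRDS(path)
  stopifnot(inherits(ws, "window_set"))
  ws
}

#' Default pipeline configuration
#'
#' All knobs of the end-to-end pipeline in one (YAML-serializable) list:
#' simulation constants, cohort size and difficulty, windowing (1,000 ms
#' windows, 800 ms look-ahead), split fractions, model families, the recall
#' target, and seeds.
#'
#' @param ... overrides for any top-level field.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    sim = unclass(sim_params()),
    cohort = list(n_pilots = 10, n_trials = 4, difficulty = c(0, 0.9)),
    window_ms = 1000, advance_ms = 800, stride_steps = 5,
    train_fraction = 0.9, folds = 10,
    families = c("STACKED_GRU", "LINEAR"),
    profile = "scaled",
    target_recall = 0.95,
    seed = 1L,
    elapsed_ms = c(0, 200, 400, 600, 800)
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> cross-validate each family -> analyze, writing
#' every artifact (trial CSVs, window container, evaluation JSON/CSV,
#' analysis CSVs, manifest) under `out_dir`.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the evaluation reports and analysis
#'   tables.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trials"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  sim_par <- do.call(sim_params, cfg$sim)

  say("[simulate] ", cfg$cohort$n_pilots, " pilots x ", cfg$cohort$n_trials,
      " trials")
  cohort <- make_cohort(cfg$cohort$n_pilots,
                        difficulty = cfg$cohort$difficulty,
                        seed = cfg$seed)
  trials <- simulate_cohort(cohort, cfg$cohort$n_trials, sim_par,
                            seed = cfg$seed)
  for (tr in trials) {
    write_trial_csv(tr, file.path(out_dir, "trials",
                                  paste0(trial_key_of(tr), ".csv")))
  }

  say("[preprocess] windows ", cfg$window_ms, " ms / advance ",
      cfg$advance_ms, " ms")
  episodes <- unlist(lapply(trials, extract_episodes), recursive = FALSE)
  ws <- make_window_set(episodes, cfg$window_ms, cfg$advance_ms,
                        cfg$stride_steps)
  sp <- split_episodes(unique(ws$meta$episode_id), cfg$train_fraction,
                       seed = cfg$seed)
  train_ws <- ws[ws$meta$episode_id %in%
                   sp$episode_id[sp$split == "TRAIN"]]
  folds <- assign_folds(unique(train_ws$meta$episode_id), cfg$folds,
                        seed = cfg$seed)
  write_windows(ws, file.path(out_dir, "windows.rds"))

  reports <- list()
  for (fam in cfg$families) {
    say("[train/evaluate] ", fam)
    spec <- if (identical(cfg$profile, "scaled")) {
      scaled_spec(fam, seed = cfg$seed)
    } else {
      model_spec(fam, seed = cfg$seed)
    }
    rep <- cross_validate(train_ws, folds, spec,
                          target_recall = cfg$target_recall,
                          verbose = verbose)
    reports[[fam]] <- rep
    jsonlite::write_json(
      list(family = fam, per_fold = rep$per_fold,
           mean_auc = rep$mean_auc, sd_auc = rep$sd_auc,
           mean_precision = rep$mean_precision,
           sd_precision = rep$sd_precision,
           best_fold = rep$best_fold),
      file.path(out_dir, "reports", paste0("cv_", tolower(fam), ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  say("[analyze] failure stratification, savability")
  best_fam <- names(reports)[which.max(vapply(reports, `[[`, numeric(1),
                                              "mean_auc"))]
  rep <- reports[[best_fam]]
  pa <- precision_at_recall(rep$predictions, cfg$target_recall)
  mis <- misclassification_by_position(rep$predictions, pa$threshold)
  djd <- djd_rate_by_prediction_type(rep$predictions, trials,
                                     cfg$advance_ms, pa$threshold)
  region <- compute_recoverable_region(sim_par)
  sav <- savable_fraction(trials, region, cfg$elapsed_ms, cfg$advance_ms)
  utils::write.csv(mis, file.path(out_dir, "reports",
                                  "misclassification_by_position.csv"),
                   row.names = FALSE)
  utils::write.csv(djd, file.path(out_dir, "reports", "djd_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(sav, file.path(out_dir, "reports", "savability.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = unclass(cfg),
    n_trials = length(trials),
    n_episodes = length(episodes),
    n_windows = length(ws$y),
    crash_window_fraction = mean(ws$y),
    families = lapply(reports, function(r)
      list(mean_auc = r$mean_auc, mean_precision = r$mean_precision)),
    best_family = best_fam,
    threshold = pa$threshold
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(reports = reports, misclassification = mis,
                 djd_rates = djd, savability = sav, region = region,
                 manifest = manifest))
}
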