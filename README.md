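# marsbalance

Simulation and crash prediction for a disorienting inverted-pendulum
balancing task.

## The problem

In a spaceflight-analog experiment, a blindfolded operator sits in a
one-axis rotating chair (a Multi-Axis Rotation System, MARS) programmed to
behave like an inverted pendulum,

&nbsp;&nbsp;&nbsp;&nbsp; θ̈ = k_P · sin θ,&nbsp;&nbsp; k_P = 600 °/s²,

and uses a joystick to hold the unstable balance point θ = 0°.  In the
horizontal roll plane gravity gives no position cue, operators drift, make
*destabilizing joystick deflections* (commands whose sign matches both the
angular position and velocity, accelerating the device toward the
boundary), and crash into the ±60° limits.  The engineering question: can a
classifier watching a short window of position, velocity and joystick data
predict a crash a fixed *time-in-advance* before it happens — and would the
warning even arrive early enough for the crash to be physically avoidable?

`marsbalance` implements that entire pipeline as a self-contained R
package, for researchers studying sensorimotor control, spatial
disorientation, or event prediction in unstable human-in-the-loop systems:

* **dynamics** — the MARS device: RK4 integration of the clamped pendulum
  ODE (|ω| ≤ 300°/s, |θ̈| ≤ 180°/s²), discrete joystick velocity
  increments, crash detection at ±60°, and 5°/s automatic resets, composed
  into 100-s balancing trials.
* **pilot** — a synthetic disoriented operator: delayed (400 ms) noisy
  velocity perception, leaky position integration (the drift mechanism),
  1–2 Hz held joystick commands with occasional sign inversions, and an
  efference-copy internal forward model whose strength is the proficiency
  axis.  `make_cohort()` spans rarely- to frequently-crashing pilots.
* **preprocess** — maximal crash-free human-controlled *episodes*, sliding
  windows (default 1,000 ms) with half-open look-ahead labels (default
  800 ms), the destabilizing-deflection Boolean channel, and episode-level
  90/10 splits and 10-fold assignments that rule out leakage.
* **predictors** — seven classifier families (linear baseline, MLP, 1-D
  CNN, LSTM, GRU, stacked LSTM, stacked GRU) on a small vectorized
  neural-network engine written in base R (Adam, binary cross-entropy,
  dropout, early stopping), with gradients verified against finite
  differences in the test suite.
* **evaluation** — pair-counting AUC, precision at a recall target
  (P@0.95R: minimize missed crashes first, then compare precision), and
  episode-grouped k-fold cross-validation.
* **crash_analysis** — misclassification stratified by peak |θ| in the
  window, destabilizing-deflection rates per prediction type, (θ, ω)
  density maps, a recoverable region computed by extremal-policy (bang-bang)
  reachability, and the savable fraction of crashes as warning time
  elapses.

## A worked example

```r
library(marsbalance)

params <- sim_params()
natural_frequency(params)
#> [1] 0.5150323        # ~0.52 Hz: the time scale the pilot must beat

cohort <- make_cohort(4, seed = 1)
trials <- simulate_cohort(cohort, n_trials = 2, params, seed = 1)
episodes <- unlist(lapply(trials, extract_episodes), recursive = FALSE)
length(episodes)
#> [1] 194

ws <- make_window_set(episodes, window_ms = 1000, advance_ms = 800,
                      stride_steps = 10)
#> 13 of 194 episodes shorter than the window; skipped
ws
#> window_set: 3146 windows of 50 steps x 4 channels (1000 ms window, 800 ms advance)
#>   crash-labeled: 579 (18.4%), episodes: 181

sp  <- split_episodes(unique(ws$meta$episode_id), 0.9, seed = 1)
tr  <- ws[ws$meta$episode_id %in% sp$episode_id[sp$split == "TRAIN"]]
folds <- assign_folds(unique(tr$meta$episode_id), k = 10, seed = 1)
rep <- cross_validate(tr, folds,
                      model_spec("STACKED_GRU", hidden = 32, head_width = 32,
                                 lr = 3e-3, lr_decay = 0.93, max_epochs = 8,
                                 seed = 1),
                      es_fraction = 0)
rep
#> eval_report: STACKED_GRU, window 1000 ms, advance 800 ms, 10 folds
#>   AUC  0.8750 +/- 0.0421
#>   P@0.95R 0.2796 +/- 0.0978 (best fold 7)
```

The AUC says the recurrent model ranks windows that precede a crash within
800 ms above the others ~88% of the time on held-out episodes (the
package's full scaled study — 10 pilots x 4 trials, as run in
`tests/testthat/test-acceptance.R` — reaches 0.91, versus 0.71 for the
linear baseline); the precision says that at the decision threshold
catching 95% of crash windows, roughly three in ten alarms are real.
Downstream,
`misclassification_by_position()`, `djd_rate_by_prediction_type()` and
`state_density_by_type()` show that the residual misses happen near 0°
where a destabilizing deflection *after* the window, invisible to any
model, causes the crash; `compute_recoverable_region()` and
`savable_fraction()` quantify how many predicted crashes were still
physically avoidable:

```r
region <- compute_recoverable_region(params)
savable_fraction(trials, region, elapsed_ms = c(0, 400, 800),
                 advance_ms = 800)
#>   elapsed_ms n_crashes pct_savable
#> 1          0       186    98.92473
#> 2        400       186    65.59140
#> 3        800       186     0.00000
```

A state on the ±60° boundary is unrecoverable by definition, so the savable
percentage at `elapsed = advance` is exactly 0 — the warning is worthless if
the entire look-ahead is consumed before anyone (or anything) acts.

A thin CLI over the same functions ships in `inst/cli/mars`
(`mars simulate | preprocess | evaluate | analyze | run`), and
`run_pipeline()` executes the whole chain from a YAML-serializable
`run_config()`.

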