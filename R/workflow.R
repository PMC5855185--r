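#' Full wavelet-scale-selection pipeline
#'
#' Runs the whole method on one channel: MVC-normalize the training and
#' validation recordings, compute per-minute Monte Carlo sensitivity
#' profiles on the training task, average them, rank the scales, build the
#' ten nested combinations, refit and evaluate every combination on the
#' validation task, and select the combination with minimal mean windowed
#' RMSE.
#'
#' @param train,validation `semg_recording`s (raw in kg, or already
#'   normalized).
#' @param calibration an [mvc_calibration()] applied to both recordings
#'   when they are not yet normalized.
#' @param channel EMG channel to analyze.
#' @param scales integer scales (default 1:10).
#' @param frame,smooth_ms feature settings (see [extract_features()]).
#' @param segment_s sensitivity segment length in seconds (default 60).
#' @param n_random Monte Carlo draws per scale (default 100,000).
#' @param window_s RMSE window in seconds (default 10).
#' @param seed optional seed for the sensitivity simulations.
#' @return list with `profiles`, `mean_sensitivity`, `ranking`, `combos`,
#'   `report` (a `selection_report`), `chosen` (a `scale_combination`),
#'   `rmse_selected` (the chosen combination's overall validation RMSE in
#'   %MVC) and `rmse_full` (same for combination I, all ten scales).
#' @export
run_scale_selection <- function(train, validation, calibration, channel,
                                scales = 1:10, frame = 200, smooth_ms = 200,
                                segment_s = 60, n_random = 1e5,
                                window_s = 10, seed = NULL) {
  if (!isTRUE(train$normalized)) train <- normalize_mvc(train, calibration)
  if (!isTRUE(validation$normalized)) {
    validation <- normalize_mvc(validation, calibration)
  }
  profiles <- sensitivity_pipeline(train, channel, scales = scales,
                                   frame = frame, smooth_ms = smooth_ms,
                                   segment_s = segment_s,
                                   n_random = n_random, seed = seed)
  mean_sens <- aggregate_sensitivity(profiles)
  ranking <- rank_scales(mean_sens)
  combos <- generate_combinations(ranking)
  fx_train <- extract_features(train, channel, scales = scales,
                               frame = frame, smooth_ms = smooth_ms)
  fx_val <- extract_features(validation, channel, scales = scales,
                             frame = frame, smooth_ms = smooth_ms)
  report <- evaluate_combinations(
    combos,
    train = list(features = fx_train$features, force = fx_train$force),
    validation = list(features = fx_val$features, force = fx_val$force),
    window_s = window_s)
  chosen <- select_combination(report)
  tab <- report$table
  list(profiles = profiles, mean_sensitivity = mean_sens,
       ranking = ranking, combos = combos, report = report,
       chosen = chosen,
       rmse_selected = tab$rmse_overall[tab$serial == chosen$serial],
       rmse_full = tab$rmse_overall[tab$ordinal == 1])
}

#' Simulated scale-selection study
#'
#' Generates a training and a validation 10-min force-varying recording
#' with the packaged synthetic generator (shared MVC calibration, as for a
#' single subject), then runs [run_scale_selection()] end to end. This is
#' the reproducible stand-in for the laboratory study: force-coupled
#' high-frequency bands, noise-only low-frequency bands, optional
#' fatigue-like drift.
#'
#' @param seed integer seed controlling every random draw (the validation
#'   recording uses a seed offset so the two recordings are independent).
#' @param train_task task of the training recording: `"force_varying"`
#'   (random-walk profile) or `"analysis"` (per-minute ramps of
#'   increasing peak, the protocol used to determine the scale
#'   combination). Validation is always a force-varying random walk.
#' @param drift_rate drift amplitude growth per minute (0 = drift-free;
#'   0.05 is the moderate-fatigue condition).
#' @param tilt_rate fractional decay of the force-coupled band gains per
#'   minute (see [generator_config()]).
#' @param unstable_gain_sd session-specific random force gain of the
#'   non-coupled bands (see [generator_config()]); 0.004 is the
#'   fatigue-corrupted condition.
#' @param duration_s recording length in seconds (default 600).
#' @param fs sampling rate (default 1000 Hz).
#' @param n_random Monte Carlo draws per scale (default 100,000).
#' @param channel synthesized channel name.
#' @param ... further arguments passed to [run_scale_selection()].
#' @return the [run_scale_selection()] result, plus `train`, `validation`
#'   and `calibration`.
#' @export
synthetic_force_study <- function(seed, drift_rate = 0, tilt_rate = 0,
                                  unstable_gain_sd = 0,
                                  duration_s = 600, fs = 1000,
                                  n_random = 1e5, channel = "emg",
                                  train_task = c("force_varying",
                                                 "analysis"), ...) {
  train_task <- match.arg(train_task)
  cfg_train <- generator_config(fs = fs, duration_s = duration_s,
                                task = train_task,
                                drift_rate = drift_rate,
                                tilt_rate = tilt_rate,
                                unstable_gain_sd = unstable_gain_sd,
                                channels = channel, seed = seed)
  cfg_val <- generator_config(fs = fs, duration_s = duration_s,
                              task = "force_varying",
                              drift_rate = drift_rate,
                              tilt_rate = tilt_rate,
                              unstable_gain_sd = unstable_gain_sd,
                              channels = channel, seed = seed + 500009L)
  train <- generate_dataset(cfg_train)
  val <- generate_dataset(cfg_val)
  res <- run_scale_selection(train$recording, val$recording,
                             train$calibration, channel,
                             n_random = n_random, seed = seed, ...)
  res$train <- train
  res$validation <- val
  res$calibration <- train$calibration
  res
}
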