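# End-to-end analysis: orientation -> Earth frame -> turn removal ->
# low-pass filter -> gait events -> stride metrics, plus cohort-scale runs
# pairing pipeline output with reference (ground-truth) metrics.

#' Pipeline configuration
#'
#' Flat key-value configuration with documented defaults; unknown keys are
#' rejected.
#'
#' @param ... Overrides of the defaults, e.g. `filter.cutoff_hz = 3`.
#'   Available keys: `filter.order` (4), `filter.cutoff_hz` (3 Hz),
#'   `orientation.mode` (`"auto"`, `"provided"` or `"complementary"`),
#'   `orientation.tilt_cutoff_hz` (0.25 Hz), `gravity.g` (9.81 m/s^2),
#'   `resample.fs_hz` (`NA` = trial nominal), `turn.window_s` (4 s),
#'   `turn.yaw_threshold_deg` (120), `turn.margin_s` (0.5 s),
#'   `events.min_prominence_factor` (0.3), `events.min_spacing_s` (0.35 s),
#'   `events.boundary_s` (0.5 s), `strides.min_s` (0.3), `strides.max_s` (3).
#' @return Named list of class `gait_config`.
#' @export
gait_config <- function(...) {
  cfg <- list(
    `filter.order` = 4L,
    `filter.cutoff_hz` = 3,
    `orientation.mode` = "auto",
    `orientation.tilt_cutoff_hz` = 0.25,
    `gravity.g` = 9.81,
    `resample.fs_hz` = NA_real_,
    `turn.window_s` = 4,
    `turn.yaw_threshold_deg` = 120,
    `turn.margin_s` = 0.5,
    `events.min_prominence_factor` = 0.3,
    `events.min_spacing_s` = 0.35,
    `events.boundary_s` = 0.5,
    `strides.min_s` = 0.3,
    `strides.max_s` = 3)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  if (!cfg$`orientation.mode` %in% c("auto", "provided", "complementary")) {
    stop("orientation.mode must be auto, provided or complementary")
  }
  structure(cfg, class = "gait_config")
}

#' Analyze one walking trial end to end
#'
#' Runs the full pipeline: per-sample attitude (trial quaternions when
#' present, otherwise the complementary-filter estimate), rotation to the
#' Earth frame with gravity removal, turn detection on the unfiltered
#' Earth-frame gyro, zero-phase low-pass filtering, straight-segment gait
#' event detection, and stride-time summarization.
#'
#' @param trial An [imu_trial()].
#' @param config A [gait_config()].
#' @return List with `metrics` (a [metrics_record()]), `events`, `turns`,
#'   `segments`, `signal` (the filtered `earth_frame_signal`) and `strides`.
#' @export
analyze_trial <- function(trial, config = gait_config()) {
  stopifnot(inherits(trial, "imu_trial"))
  mode <- config$`orientation.mode`
  if (mode == "provided" && is.null(trial$quat)) {
    stop("orientation.mode = 'provided' but the trial carries no quaternions")
  }
  quat <- if (mode == "complementary") {
    tr <- trial; tr$quat <- NULL
    estimate_orientation(tr, tilt_cutoff_hz = config$`orientation.tilt_cutoff_hz`)
  } else {
    estimate_orientation(trial, tilt_cutoff_hz = config$`orientation.tilt_cutoff_hz`)
  }
  fs <- config$`resample.fs_hz`
  sig <- rotate_to_earth(trial, quat, fs = if (is.na(fs)) NULL else fs,
                         g = config$`gravity.g`)
  turns <- detect_turns(sig, window_s = config$`turn.window_s`,
                        yaw_threshold_deg = config$`turn.yaw_threshold_deg`)
  filt <- lowpass(sig, cutoff = config$`filter.cutoff_hz`,
                  order = config$`filter.order`)
  segs <- straight_segments(filt, turns, margin_s = config$`turn.margin_s`)
  events <- detect_gait_events(
    filt, segs,
    min_prominence_factor = config$`events.min_prominence_factor`,
    min_spacing_s = config$`events.min_spacing_s`,
    boundary_s = config$`events.boundary_s`)
  strides <- stride_series(events, min_s = config$`strides.min_s`,
                           max_s = config$`strides.max_s`)
  metrics <- summarize_strides(strides, trial_id = trial$trial_id,
                               condition = trial$condition)
  metrics$flags <- unique(c(metrics$flags, trial$flags))
  list(metrics = metrics, events = events, turns = turns, segments = segs,
       signal = filt, strides = strides)
}

#' Analyze a simulated cohort and pair pipeline with reference metrics
#'
#' Runs [analyze_trial()] on every simulated trial and computes the matched
#' reference metrics from the simulator ground truth (standing in for the
#' gold-standard system), one row per trial.
#'
#' @param sim Output of [simulate_cohort()] (or a flat trial list as from
#'   [simulate_participant()]).
#' @param config A [gait_config()].
#' @return data.frame with per-trial pipeline (`pipe_*`) and reference
#'   (`ref_*`) stride-time metrics.
#' @export
run_cohort_analysis <- function(sim, config = gait_config()) {
  trials <- if (!is.null(sim$trials)) sim$trials else sim
  rows <- lapply(trials, function(el) {
    res <- analyze_trial(el$trial, config)
    ref <- ground_truth_metrics(el$truth,
                                turn_margin_s = config$`turn.margin_s`,
                                boundary_s = config$`events.boundary_s`,
                                trial_id = el$trial$trial_id,
                                condition = el$condition)
    data.frame(participant_id = el$participant_id,
               condition = el$condition,
               trial_index = el$trial_index,
               pipe_n_strides = res$metrics$n_strides,
               pipe_stride_time_mean = res$metrics$stride_time_mean,
               pipe_stride_time_sd = res$metrics$stride_time_sd,
               pipe_variability = res$metrics$stride_time_variability,
               ref_n_strides = ref$n_strides,
               ref_stride_time_mean = ref$stride_time_mean,
               ref_stride_time_sd = ref$stride_time_sd,
               ref_variability = ref$stride_time_variability,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant, per-condition averages of a cohort run
#'
#' Averages the per-trial pipeline and reference metrics across each
#' participant's repeated trials within condition, as the study protocol
#' averages its two assessments.
#'
#' @param run data.frame from [run_cohort_analysis()].
#' @return data.frame with one row per participant-condition.
#' @export
participant_summary <- function(run) {
  agg <- stats::aggregate(
    run[, c("pipe_stride_time_mean", "pipe_stride_time_sd",
            "pipe_variability", "ref_stride_time_mean", "ref_stride_time_sd",
            "ref_variability")],
    by = list(participant_id = run$participant_id, condition = run$condition),
    FUN = mean)
  agg[order(agg$participant_id, agg$condition), ]
}

#' Validity statistics of a cohort run
#'
#' Pearson validity of pipeline stride time and stride time variability
#' against the reference, per condition, on participant-level averages.
#'
#' @param run data.frame from [run_cohort_analysis()].
#' @return List of `validity_result` objects named
#'   `<metric>.<condition>`.
#' @export
validity_from_run <- function(run) {
  ps <- participant_summary(run)
  out <- list()
  for (cond in CONDITIONS) {
    d <- ps[ps$condition == cond, ]
    if (!nrow(d)) next
    out[[paste0("stride_time.", cond)]] <-
      validity(d$pipe_stride_time_mean, d$ref_stride_time_mean,
               metric = "stride_time", condition = cond)
    out[[paste0("variability.", cond)]] <-
      validity(d$pipe_variability, d$ref_variability,
               metric = "stride_time_variability", condition = cond)
  }
  out
}

#' Simulate a cohort and measure pipeline validity against ground truth
#'
#' Convenience wrapper used by the worked examples and the acceptance
#' script: simulates `n_participants` x 2 conditions x `n_trials` trials,
#' analyzes every trial, and returns the per-trial run table, the
#' participant summary and the per-condition validity results.
#'
#' @param n_participants Cohort size (default 52).
#' @param seed Integer seed for the simulation.
#' @param n_trials Trials per participant per condition.
#' @param config A [gait_config()].
#' @param ... Passed on to [simulate_cohort()].
#' @return List with `sim`, `run`, `summary`, `validity`.
#' @export
run_validity_study <- function(n_participants = 52, seed = 1, n_trials = 2,
                               config = gait_config(), ...) {
  sim <- simulate_cohort(n_participants = n_participants, seed = seed,
                         n_trials = n_trials, ...)
  run <- run_cohort_analysis(sim, config)
  list(sim = sim, run = run, summary = participant_summary(run),
       validity = validity_from_run(run))
}

#' Stack a cohort run into the long table used by the condition ANOVA
#'
#' @param run data.frame from [run_cohort_analysis()].
#' @param cohort Cohort covariate table (from [simulate_cohort()], or any
#'   data.frame with `participant_id`, `age`, `sex`, `education_years`).
#' @return Long data.frame: one row per participant-condition with
#'   `stride_time_mean`, `stride_time_variability` and covariates.
#' @export
cohort_long_metrics <- function(run, cohort) {
  ps <- participant_summary(run)
  long <- merge(ps, cohort[, c("participant_id", "age", "sex",
                               "education_years")],
                by = "participant_id")
  data.frame(participant_id = long$participant_id,
             condition = long$condition,
             stride_time_mean = long$pipe_stride_time_mean,
             stride_time_variability = long$pipe_variability,
             age = long$age, sex = long$sex,
             education_years = long$education_years,
             stringsAsFactors = FALSE)
}
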