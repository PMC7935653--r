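# Synthetic pocket-IMU walking trials with exact, closed-form ground truth.
#
# Protocol emulated: walk ~10 m down a straight hallway, turn 180 degrees,
# walk ~10 m back, phone in a trouser pocket at an arbitrary fixed
# orientation. The vertical Earth-frame acceleration is a two-harmonic
# waveform with two peaks per stride whose amplitudes alternate high/low
# (the phone-side and contralateral steps); heel strikes are the analytic
# trough nadirs following the high peaks, so event ground truth is exact and
# never itself "detected" — no circularity between simulator and detector.

#' Parameters of the walking-trial simulator
#'
#' Defaults are the cohort-typical single-task study conditions: mean stride
#' time 1.09 s, stride-time CV 3%, 10 m straight legs at 1.1 m/s, a 2.5 s
#' 180-degree mid-trial turn, and the standard noise fixture
#' (base amplitude 2.5 m/s^2, step asymmetry 0.35, white noise SD
#' 0.15 on all channels).
#'
#' @param stride_time_mean Mean stride duration (s), in \[0.6, 2\].
#' @param stride_time_cv Coefficient of variation of stride durations
#'   (fraction, in \[0, 0.2\]); draws are truncated at 3 SD.
#' @param step_asymmetry High/low peak amplitude contrast (fraction).
#' @param base_amp Vertical acceleration amplitude (m/s^2).
#' @param noise_sd White Gaussian noise SD added to all six device channels
#'   (m/s^2 for acceleration, rad/s for angular rate).
#' @param walk_speed Walking speed (m/s); with stride time it sets strides
#'   per leg.
#' @param course_length Length of each straight leg (m).
#' @param turn_duration Duration of the 180-degree turn (s).
#' @param turn_angle Turn magnitude (deg).
#' @param device_quat Fixed pocket attitude: unit quaternion rotating the
#'   device frame into the body frame (scalar-first).
#' @param fs Sampling rate (Hz).
#' @param attach_quat Attach the true per-sample device-to-Earth quaternions
#'   to the generated trial (as an OS attitude API would)?
#' @param lead_s,tail_s Quiet standing before/after the walk (s).
#' @param condition Trial condition label.
#' @return Validated list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(stride_time_mean = 1.09, stride_time_cv = 0.03,
                            step_asymmetry = 0.35, base_amp = 2.5,
                            noise_sd = 0.15, walk_speed = 1.1,
                            course_length = 10, turn_duration = 2.5,
                            turn_angle = 180, device_quat = c(1, 0, 0, 0),
                            fs = 100, attach_quat = FALSE, lead_s = 1,
                            tail_s = 1, condition = "single_task") {
  if (stride_time_mean < 0.6 || stride_time_mean > 2) {
    stop("stride_time_mean must lie in [0.6, 2] s")
  }
  if (stride_time_cv < 0 || stride_time_cv > 0.2) {
    stop("stride_time_cv must lie in [0, 0.2]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (step_asymmetry < 0 || step_asymmetry >= 1) {
    stop("step_asymmetry must lie in [0, 1)")
  }
  if (walk_speed <= 0 || course_length <= 0 || turn_duration <= 0 || fs <= 0) {
    stop("walk_speed, course_length, turn_duration and fs must be positive")
  }
  device_quat <- quat_normalize(as.numeric(device_quat))
  structure(as.list(environment()), class = "gait_sim_params")
}

# cosine blend 0 -> 1 over [a, b]
cos_ramp <- function(t, a, b) {
  u <- pmin(1, pmax(0, (t - a) / (b - a)))
  0.5 * (1 - cos(pi * u))
}

#' Simulate one pocket-IMU walking trial with exact ground truth
#'
#' Stride durations are drawn i.i.d. Normal (truncated at 3 SD) and chained
#' into a phase clock advancing 2*pi per stride. The vertical Earth-frame
#' acceleration is `base_amp * (cos(2*phase) + step_asymmetry * cos(phase))`
#' — two peaks per stride with alternating amplitudes — damped 50% during
#' the turn. The turn is a raised-cosine yaw-rate pulse integrating exactly
#' to `turn_angle`. Every sample is finally rotated from the Earth frame into
#' the device frame (fixed pocket attitude composed with the walker's
#' heading), gravity is added, and white noise is applied.
#'
#' @param params A [gait_sim_params()] object.
#' @param seed Integer seed (the function sets the RNG); `NULL` uses the
#'   current stream.
#' @param trial_id Identifier for the generated trial.
#' @return List with `trial` (an [imu_trial()]) and `truth` (class
#'   `gait_ground_truth`: `heel_strikes`, `toe_offs`, `stride_times`
#'   (= diff of heel strikes), `turn_interval`, `gait_span`, `device_quat`,
#'   `earth_vertical_acc`, `t`, `params`).
#' @export
simulate_trial <- function(params = gait_sim_params(), seed = NULL,
                           trial_id = "sim") {
  stopifnot(inherits(params, "gait_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  draw_strides <- function(total_needed, by_distance) {
    d <- numeric(0)
    acc <- 0
    while (acc < total_needed) {
      z <- max(-3, min(3, stats::rnorm(1)))
      s <- p$stride_time_mean * (1 + p$stride_time_cv * z)
      d <- c(d, s)
      acc <- acc + if (by_distance) p$walk_speed * s else s
    }
    d
  }
  leg1 <- draw_strides(p$course_length, TRUE)
  turn_str <- draw_strides(p$turn_duration, FALSE)
  leg2 <- draw_strides(p$course_length, TRUE)
  durs <- c(leg1, turn_str, leg2)
  gait_start <- p$lead_s
  bounds <- gait_start + c(0, cumsum(durs))   # stride boundaries
  gait_end <- bounds[length(bounds)]
  turn_start <- gait_start + sum(leg1)
  turn_end <- turn_start + p$turn_duration
  total <- gait_end + p$tail_s
  n <- as.integer(round(total * p$fs)) + 1L
  t <- (0:(n - 1L)) / p$fs

  # phase clock: 2*pi per stride, piecewise linear, frozen outside the walk
  idx <- findInterval(t, bounds, rightmost.closed = TRUE)
  phase <- numeric(n)
  inw <- idx >= 1L & idx <= length(durs)
  phase[inw] <- 2 * pi * (idx[inw] - 1) +
    2 * pi * (t[inw] - bounds[idx[inw]]) / durs[idx[inw]]
  phase[t >= gait_end] <- 2 * pi * length(durs)

  # amplitude envelope: ramps at gait start/end, 50% damping during the turn
  r <- 0.3
  env <- cos_ramp(t, gait_start, gait_start + r) *
    (1 - cos_ramp(t, gait_end - r, gait_end))
  turn_blend <- cos_ramp(t, turn_start - r / 2, turn_start + r / 2) *
    (1 - cos_ramp(t, turn_end - r / 2, turn_end + r / 2))
  env <- env * (1 - 0.5 * turn_blend)

  a <- p$step_asymmetry
  vert <- env * p$base_amp * (cos(2 * phase) + a * cos(phase))

  # heading: raised-cosine yaw-rate pulse integrating to turn_angle
  theta <- p$turn_angle * pi / 180
  u <- pmin(1, pmax(0, (t - turn_start) / p$turn_duration))
  yaw_rate <- (2 * theta / p$turn_duration) * 0.5 * (1 - cos(2 * pi * u)) *
    (t >= turn_start & t <= turn_end)
  psi <- theta * (u - sin(2 * pi * u) / (2 * pi))

  # body-frame horizontal gait accelerations (AP at step rate, ML at stride rate)
  ap <- 1.0 * env * sin(2 * phase + 0.7)
  ml <- 0.5 * env * sin(phase + 1.3)
  acc_e <- cbind(cos(psi) * ap - sin(psi) * ml,
                 sin(psi) * ap + cos(psi) * ml,
                 vert)
  gyro_e <- cbind(0.3 * env * sin(2 * phase + 0.4),
                  0.2 * env * sin(phase + 1.0),
                  yaw_rate + 0.1 * env * sin(phase + 0.5))

  # device->Earth attitude: walker heading composed with the pocket attitude
  q_true <- quat_multiply(quat_yaw(psi), p$device_quat)
  g <- 9.81
  acc_dev <- quat_rotate(quat_conjugate(q_true),
                         cbind(acc_e[, 1], acc_e[, 2], acc_e[, 3] + g))
  gyro_dev <- quat_rotate(quat_conjugate(q_true), gyro_e)
  if (p$noise_sd > 0) {
    acc_dev <- acc_dev + matrix(stats::rnorm(3 * n, sd = p$noise_sd), n, 3)
    gyro_dev <- gyro_dev + matrix(stats::rnorm(3 * n, sd = p$noise_sd), n, 3)
  }

  trial <- imu_trial(trial_id = trial_id, condition = p$condition, t = t,
                     acc = acc_dev, gyro = gyro_dev,
                     quat = if (p$attach_quat) q_true else NULL,
                     fs_nominal = p$fs,
                     meta = list(simulated = TRUE))

  # analytic event times: d/dphase [cos(2*phi) + a*cos(phi)] = 0 at
  # cos(phi) = -a/4; the trough after the high peak (phi = 0) is the heel
  # strike, the one after the low peak (phi = pi) the toe-off
  th_hs <- if (a > 0) acos(-a / 4) else pi / 2
  th_to <- 2 * pi - th_hs
  hs <- bounds[seq_along(durs)] + durs * th_hs / (2 * pi)
  toff <- bounds[seq_along(durs)] + durs * th_to / (2 * pi)
  truth <- structure(list(heel_strikes = hs, toe_offs = toff,
                          stride_times = diff(hs),
                          turn_interval = c(turn_start, turn_end),
                          gait_span = c(gait_start, gait_end),
                          device_quat = p$device_quat,
                          earth_vertical_acc = vert, t = t,
                          params = p),
                     class = "gait_ground_truth")
  list(trial = trial, truth = truth)
}

#' Reference gait metrics from simulator ground truth
#'
#' Plays the role of the gold-standard reference system: computes the same
#' stride-time summary as the pipeline, from the true heel strikes, after
#' excluding the dilated turn interval and trial-boundary margins exactly as
#' the analysis protocol does.
#'
#' @param truth A `gait_ground_truth`.
#' @param turn_margin_s Dilation around the true turn interval (s).
#' @param boundary_s Margin trimmed at the start/end of the walk (s).
#' @param trial_id,condition Identity for the returned record.
#' @return A [metrics_record()].
#' @export
ground_truth_metrics <- function(truth, turn_margin_s = 0.5, boundary_s = 0.5,
                                 trial_id = "truth",
                                 condition = "single_task") {
  stopifnot(inherits(truth, "gait_ground_truth"))
  hs <- truth$heel_strikes
  lo <- truth$gait_span[1] + boundary_s
  hi <- truth$gait_span[2] - boundary_s
  a <- truth$turn_interval[1] - turn_margin_s
  b <- truth$turn_interval[2] + turn_margin_s
  keep <- hs >= lo & hs <= hi
  pre <- hs[keep & hs < a]
  post <- hs[keep & hs > b]
  st <- c(if (length(pre) >= 2) diff(pre), if (length(post) >= 2) diff(post))
  summarize_strides(st, trial_id = trial_id, condition = condition)
}

#' Simulate one participant: paired single-/dual-task trials
#'
#' @param params_single,params_dual [gait_sim_params()] for each condition;
#'   the dual-task default applies the cohort-typical shifts (mean stride
#'   time 1.17 s, larger variability).
#' @param n_trials Repeated assessments (default 2, as in the protocol).
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @param participant_id Identifier used in trial ids.
#' @param random_pocket Draw a fresh random fixed pocket attitude for every
#'   trial (the phone lands differently each time it is pocketed)? When
#'   `FALSE` the `device_quat` of the supplied parameters is used.
#' @return List of `n_trials * 2` elements, each with `trial`, `truth`,
#'   `condition`, `trial_index`, `participant_id`.
#' @export
simulate_participant <- function(params_single = gait_sim_params(),
                                 params_dual = gait_sim_params(
                                   stride_time_mean = 1.17,
                                   stride_time_cv = 0.05,
                                   condition = "dual_task"),
                                 n_trials = 2, seed = 1,
                                 participant_id = "P01",
                                 random_pocket = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_trials)
  pocket <- quat_random(2L * n_trials)
  out <- list()
  k <- 0L
  for (tr in seq_len(n_trials)) {
    for (cond in c("single_task", "dual_task")) {
      k <- k + 1L
      p <- if (cond == "single_task") params_single else params_dual
      p$condition <- cond
      if (random_pocket) p$device_quat <- pocket[k, ]
      sim <- simulate_trial(p, seed = seeds[k],
                            trial_id = sprintf("%s_%s_t%d", participant_id,
                                               cond, tr))
      out[[k]] <- c(sim, list(condition = cond, trial_index = tr,
                              participant_id = participant_id))
    }
  }
  out
}

#' Simulate a cohort with latent-severity associations
#'
#' Per-participant gait parameters and clinical scores are driven by a
#' latent severity factor: stride-time variability increases with severity,
#' and each clinical score is generated with the standardized effect given in
#' `effect_spec` (UPDRS III, HAM-A, HAM-D positive; MoCA negative), around
#' cohort-typical means and SDs. Age, sex and education are drawn from
#' cohort-typical distributions.
#'
#' @param n_participants Number of participants (default 52). Fewer than 10
#'   flags a warning (regressions unstable).
#' @param effect_spec Named numeric vector/list of standardized effects of
#'   latent severity on `updrs3`, `moca`, `hama`, `hamd` (each in \[-1, 1\]).
#' @param seed Integer seed.
#' @param n_trials Trials per participant per condition (default 2).
#' @param attach_quat Attach true attitude quaternions to the trials.
#' @param base_single,base_dual Template [gait_sim_params()] whose
#'   non-gait-parameter fields (noise, geometry, fs, ...) are used for all
#'   participants.
#' @param cv_mean,cv_sd Mean and SD of the single-task stride-time CV across
#'   participants (fractions); dual-task CV is 1.6x the single-task CV.
#' @return List with `cohort` (data.frame: `participant_id, age, sex,
#'   education_years, updrs3, moca, hama, hamd` plus the true per-participant
#'   gait parameters) and `trials` (flat list as in
#'   [simulate_participant()]).
#' @export
simulate_cohort <- function(n_participants = 52,
                            effect_spec = c(updrs3 = 0.39, moca = -0.48,
                                            hama = 0.49, hamd = 0.44),
                            seed = 1, n_trials = 2, attach_quat = FALSE,
                            base_single = gait_sim_params(),
                            base_dual = gait_sim_params(
                              stride_time_mean = 1.17, stride_time_cv = 0.05,
                              condition = "dual_task"),
                            cv_mean = 0.035, cv_sd = 0.02) {
  set.seed(seed)
  n <- n_participants
  if (n < 10) warning("fewer than 10 participants: association models will be unstable")
  eff <- as.list(effect_spec)
  for (k in c("updrs3", "moca", "hama", "hamd")) eff[[k]] <- eff[[k]] %||% 0
  severity <- stats::rnorm(n)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  score <- function(beta, mu, sdev) {
    mu + sdev * (beta * severity +
                   sqrt(max(0, 1 - beta^2)) * stats::rnorm(n))
  }
  cohort <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    age = clamp(round(stats::rnorm(n, 63, 10)), 40, 83),
    sex = ifelse(stats::runif(n) < 0.37, "female", "male"),
    education_years = clamp(round(stats::rnorm(n, 11, 3)), 3, 22),
    updrs3 = score(eff$updrs3, 38.3, 15.1),
    moca = score(eff$moca, 22, 4),
    hama = score(eff$hama, 11.8, 4),
    hamd = score(eff$hamd, 11.1, 5.1),
    stringsAsFactors = FALSE)
  cohort$stride_time_single_s <- clamp(stats::rnorm(n, 1.09, 0.08), 0.8, 1.5)
  cohort$stride_time_dual_s <- clamp(
    cohort$stride_time_single_s + stats::rnorm(n, 0.08, 0.03), 0.8, 1.8)
  cohort$stride_cv_single <- clamp(cv_mean + cv_sd * severity, 0.008, 0.12)
  cohort$stride_cv_dual <- clamp(1.6 * cohort$stride_cv_single, 0.01, 0.15)
  cohort$severity <- severity
  part_seeds <- sample.int(.Machine$integer.max - 1L, n)
  trials <- list()
  for (i in seq_len(n)) {
    ps <- base_single; pd <- base_dual
    ps$stride_time_mean <- cohort$stride_time_single_s[i]
    ps$stride_time_cv <- cohort$stride_cv_single[i]
    pd$stride_time_mean <- cohort$stride_time_dual_s[i]
    pd$stride_time_cv <- cohort$stride_cv_dual[i]
    ps$attach_quat <- attach_quat; pd$attach_quat <- attach_quat
    trials <- c(trials,
                simulate_participant(ps, pd, n_trials = n_trials,
                                     seed = part_seeds[i],
                                     participant_id = cohort$participant_id[i]))
  }
  list(cohort = cohort, trials = trials)
}
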