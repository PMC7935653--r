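test_that("no angular velocity means no turns", {
  sig <- make_signal((0:1999) / 100, matrix(0, 2000, 3), matrix(0, 2000, 3),
                     fs = 100)
  expect_identical(nrow(detect_turns(sig)), 0L)
})

test_that("a simulated 180-degree turn is localized within 0.3 s at each edge", {
  for (seed in c(2, 3, 4)) {
    sim <- simulate_trial(gait_sim_params(device_quat = quat_random(1)[1, ]),
                          seed = seed)
    sig <- rotate_to_earth(sim$trial, estimate_orientation(sim$trial))
    turns <- detect_turns(sig)
    expect_identical(nrow(turns), 1L)
    expect_lt(abs(turns$t_start - sim$truth$turn_interval[1]), 0.3)
    expect_lt(abs(turns$t_end - sim$truth$turn_interval[2]), 0.3)
    expect_gt(abs(turns$yaw_change_deg), 120)
  }
})

test_that("two separated turns are both detected in order", {
  fs <- 100
  t <- (0:3999) / fs
  pulse <- function(t0, dur) {
    u <- pmin(1, pmax(0, (t - t0) / dur))
    (2 * pi / dur) * 0.5 * (1 - cos(2 * pi * u)) * (t >= t0 & t <= t0 + dur)
  }
  gz <- pulse(8, 2.5) + pulse(25, 2.5)  # two 180-degree turns, 8+ s apart
  sig <- make_signal(t, matrix(0, 4000, 3), cbind(0, 0, gz), fs = fs)
  turns <- detect_turns(sig)
  expect_identical(nrow(turns), 2L)
  expect_lt(abs(turns$t_start[1] - 8), 0.4)
  expect_lt(abs(turns$t_start[2] - 25), 0.4)
  expect_true(turns$t_end[1] < turns$t_start[2])
})

test_that("straight segments are the complement of dilated turns", {
  sig <- make_signal((0:2999) / 100, matrix(0, 3000, 3), matrix(0, 3000, 3),
                     fs = 100)
  # no turns: full span
  full <- straight_segments(sig, NULL)
  expect_equal(full$t_start, 0)
  expect_equal(full$t_end, 29.99)
  # one mid-trial turn: two segments, neither touching the dilated turn
  turns <- data.frame(t_start = 14, t_end = 16, yaw_change_deg = 180)
  segs <- straight_segments(sig, turns, margin_s = 0.5)
  expect_identical(nrow(segs), 2L)
  expect_lte(segs$t_end[1], 13.5)
  expect_gte(segs$t_start[2], 16.5)
})

test_that("interval complement equals a brute-force boolean-mask oracle", {
  set.seed(42)
  fs <- 100
  t <- (0:4999) / fs
  sig <- make_signal(t, matrix(0, 5000, 3), matrix(0, 5000, 3), fs = fs)
  for (rep in 1:10) {
    k <- sample(0:3, 1)
    starts <- sort(runif(k, 2, 45))
    turns <- data.frame(t_start = starts, t_end = starts + runif(k, 1, 3),
                        yaw_change_deg = rep(180, k))
    margin <- 0.5
    segs <- straight_segments(sig, turns, margin_s = margin, min_len_s = 3)
    # oracle: per-sample mask, runs of clear samples
    mask <- rep(TRUE, length(t))
    for (i in seq_len(k)) {
      mask[t >= turns$t_start[i] - margin & t <= turns$t_end[i] + margin] <- FALSE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts_i <- ends - r$lengths + 1
    keep <- r$values & (t[ends] - t[starts_i] >= 3)
    expect_equal(nrow(segs), sum(keep))
    if (sum(keep)) {
      expect_equal(segs$t_start, t[starts_i[keep]], tolerance = 1.5 / fs)
      expect_equal(segs$t_end, t[ends[keep]], tolerance = 1.5 / fs)
    }
  }
})

test_that("a flat signal yields an insufficient-gait error", {
  sig <- make_signal((0:999) / 100, matrix(0, 1000, 3), matrix(0, 1000, 3),
                     fs = 100, filtered = TRUE, cutoff = 3)
  segs <- data.frame(t_start = 0, t_end = 9.99)
  expect_error(detect_gait_events(sig, segs), "insufficient gait")
  # and unfiltered input is refused outright
  sig$filtered <- FALSE
  expect_error(detect_gait_events(sig, segs), "filtered")
})

test_that("noiseless heel strikes equal the analytic trough times", {
  sim <- simulate_trial(gait_sim_params(noise_sd = 0), seed = 9)
  sig <- lowpass(rotate_to_earth(sim$trial, estimate_orientation(sim$trial)))
  turns <- detect_turns(sig)
  segs <- straight_segments(sig, turns)
  ev <- detect_gait_events(sig, segs)
  truth <- guarded_truth_hs(sim$truth)
  # steady straight walking (away from turn/boundary amplitude ramps):
  # detected troughs coincide with the analytic ones within one sample
  steady <- ev$heel_strikes[vapply(ev$heel_strikes,
                                   function(h) min(abs(truth - h)) < 0.1,
                                   logical(1))]
  d <- nearest_match(steady, truth)
  expect_lt(max(d), 0.010)
  expect_gte(length(steady), length(truth) - 1)
})

test_that("default-fixture heel strikes match ground truth 1:1 within 30 ms", {
  for (seed in c(13, 14)) {
    sim <- simulate_trial(gait_sim_params(device_quat = quat_random(1)[1, ]),
                          seed = seed)
    res <- analyze_trial(sim$trial)
    hs <- res$events$heel_strikes
    # no spurious events: every detection near some true heel strike
    expect_lt(max(nearest_match(hs, sim$truth$heel_strikes)), 0.030)
    # every guarded true heel strike recovered exactly once
    truth <- guarded_truth_hs(sim$truth)
    m <- vapply(truth, function(h) sum(abs(hs - h) < 0.030), numeric(1))
    expect_true(all(m == 1))
  }
})

test_that("retained peak classes strictly alternate within each segment", {
  for (seed in 31:35) {
    sim <- simulate_trial(quick_params(stride_time_cv = 0.06,
                                       device_quat = quat_random(1)[1, ]),
                          seed = seed)
    ev <- analyze_trial(sim$trial)$events
    for (si in unique(ev$peaks$segment)) {
      cls <- ev$peaks$class[ev$peaks$segment == si]
      expect_true(all(cls[-1] != cls[-length(cls)]))
    }
  }
})

test_that("no detected event lies inside a dilated turn interval", {
  for (seed in 41:44) {
    sim <- simulate_trial(gait_sim_params(device_quat = quat_random(1)[1, ]),
                          seed = seed)
    res <- analyze_trial(sim$trial)
    for (i in seq_len(nrow(res$turns))) {
      a <- res$turns$t_start[i] - 0.5
      b <- res$turns$t_end[i] + 0.5
      ev <- c(res$events$heel_strikes, res$events$toe_offs)
      expect_false(any(ev > a & ev < b))
    }
  }
})
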