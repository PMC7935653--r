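# Shared fixtures: all test data is generated in code.

# short, fast trial parameters (one ~6 m leg each way keeps trials ~14 s)
quick_params <- function(...) {
  gait_sim_params(course_length = 6, ...)
}

# bare Earth-frame signal object for unit tests that bypass the rotation step
make_signal <- function(t, acc, gyro, fs, filtered = FALSE, cutoff = NA_real_) {
  structure(list(t = t, acc = acc, gyro = gyro, fs = fs,
                 filtered = filtered, cutoff = cutoff, g = 9.81),
            class = "earth_frame_signal")
}

# static-phone trial with constant device-frame acceleration
static_trial <- function(acc_vec, duration = 3, fs = 100,
                         condition = "single_task") {
  n <- duration * fs + 1
  t <- (0:(n - 1)) / fs
  imu_trial("static", condition, t,
            acc = matrix(rep(acc_vec, each = n), n, 3),
            gyro = matrix(0, n, 3), fs_nominal = fs)
}

# match each detected event to the nearest true event; returns match distances
nearest_match <- function(detected, truth) {
  vapply(detected, function(d) min(abs(truth - d)), numeric(1))
}

# true heel strikes inside the evaluation region: away from trial boundaries
# and the (dilated + worst-case localisation inset) true turn interval
guarded_truth_hs <- function(truth, guard = 0.75) {
  hs <- truth$heel_strikes
  keep <- hs >= truth$gait_span[1] + guard & hs <= truth$gait_span[2] - guard &
    (hs <= truth$turn_interval[1] - guard | hs >= truth$turn_interval[2] + guard)
  hs[keep]
}
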