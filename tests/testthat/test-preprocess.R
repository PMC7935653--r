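test_that("quaternion algebra matches closed-form rotations", {
  set.seed(1)
  # 90 degrees about X maps Y onto Z
  q <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  expect_equal(quat_rotate(q, c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  # composition equals sequential rotation; conjugate inverts
  q1 <- quat_random(1)[1, ]; q2 <- quat_random(1)[1, ]
  v <- rnorm(3)
  expect_equal(quat_rotate(quat_multiply(q2, q1), v),
               quat_rotate(q2, quat_rotate(q1, v)), tolerance = 1e-12)
  expect_equal(quat_rotate(quat_conjugate(q1), quat_rotate(q1, v)), v,
               tolerance = 1e-12)
  expect_equal(quat_rotate(quat_between(v, c(0, 0, 1)), v),
               c(0, 0, sqrt(sum(v^2))), tolerance = 1e-12)
})

test_that("orientation estimation passes provided quaternions through", {
  sim <- simulate_trial(quick_params(attach_quat = TRUE), seed = 5)
  expect_identical(estimate_orientation(sim$trial), sim$trial$quat)
})

test_that("static phone attitudes are recovered up to yaw", {
  # lying flat: gravity already vertical
  flat <- static_trial(c(0, 0, 9.81))
  qf <- estimate_orientation(flat)
  sigf <- rotate_to_earth(flat, qf)
  expect_lt(max(abs(sigf$acc[, 3])), 1e-6)
  # rotated 90 degrees about device X: acc = (0, 9.81, 0) must map onto Z
  tilted <- static_trial(c(0, 9.81, 0))
  qt <- estimate_orientation(tilted)
  sigt <- rotate_to_earth(tilted, qt, g = 0)
  expect_equal(sigt$acc[100, ], c(0, 0, 9.81), tolerance = 1e-6)
})

test_that("free-fall-like input is rejected", {
  tr <- static_trial(c(0, 0, 1e-4))
  expect_error(estimate_orientation(tr), "free-fall")
})

test_that("rotation is an isometry on every sample", {
  sim <- simulate_trial(quick_params(device_quat = c(0.5, -0.5, 0.5, 0.5)),
                        seed = 21)
  q <- estimate_orientation(sim$trial)
  sig <- rotate_to_earth(sim$trial, q, g = 0)
  # oracle: device-frame norms on the same uniform grid
  dev <- vapply(1:3, function(j) {
    approx(sim$trial$t, sim$trial$acc[, j], xout = sig$t)$y
  }, numeric(length(sig$t)))
  expect_lt(max(abs(sqrt(rowSums(sig$acc^2)) - sqrt(rowSums(dev^2)))), 1e-9)
})

test_that("estimated orientation recovers the Earth-frame vertical under a random fixed pocket attitude", {
  set.seed(33)
  for (rep in 1:3) {
    qd <- quat_random(1)[1, ]
    sim <- simulate_trial(quick_params(noise_sd = 0, device_quat = qd),
                          seed = 100 + rep)
    q <- estimate_orientation(sim$trial)
    sig <- rotate_to_earth(sim$trial, q)
    rmse <- sqrt(mean((sig$acc[, 3] - sim$truth$earth_vertical_acc)^2))
    expect_lt(rmse, 0.05)
  }
})

test_that("gravity-removed vertical acceleration has near-zero mean during walking", {
  sim <- simulate_trial(gait_sim_params(device_quat = quat_random(1)[1, ]),
                        seed = 77)
  sig <- rotate_to_earth(sim$trial, estimate_orientation(sim$trial))
  walking <- sig$t > sim$truth$gait_span[1] & sig$t < sim$truth$gait_span[2]
  expect_lt(abs(mean(sig$acc[walking, 3])), 0.1)
})

test_that("zero-phase Butterworth filter matches its analytic magnitude response", {
  fs <- 100; cutoff <- 3; order <- 4
  # DC: unit gain
  dc <- make_signal(t = (0:999) / fs, acc = matrix(2.5, 1000, 3),
                    gyro = matrix(-1, 1000, 3), fs = fs)
  out <- lowpass(dc, cutoff, order)
  expect_lt(max(abs(out$acc - 2.5)), 1e-9)
  expect_true(out$filtered)
  expect_equal(out$cutoff, cutoff)

  # analytic two-pass gain of the bilinear-transform Butterworth design
  gain2 <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
  measure <- function(f) {
    t <- (0:2999) / fs
    x <- sin(2 * pi * f * t)
    sig <- make_signal(t, acc = cbind(x, x, x), gyro = cbind(x, x, x), fs = fs)
    y <- lowpass(sig, cutoff, order)$acc[, 3]
    mid <- 1000:2000
    fit <- lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid]) - 1)
    sqrt(sum(coef(fit)^2))
  }
  passband <- c(0.3, 0.6, 1, 1.4, 1.8, 2.2)
  for (f in passband) expect_equal(measure(f), gain2(f), tolerance = 0.02)
  stopband <- c(6, 8, 10, 12)
  m <- vapply(stopband, measure, numeric(1))
  expect_true(all(diff(m) < 0))               # attenuation ordering
  expect_lt(m[3], 1.05 * gain2(10))           # below the closed-form bound
  # 1 Hz sinusoid passes within 1%
  expect_equal(measure(1), 1, tolerance = 0.01)
})

test_that("filtering rejects sampling rates at or below twice the cutoff", {
  sig <- make_signal((0:99) / 5, matrix(0, 100, 3), matrix(0, 100, 3), fs = 5)
  expect_error(lowpass(sig, cutoff = 3), "twice the cutoff")
})

test_that("pipeline metrics are invariant to the fixed pocket orientation", {
  set.seed(8)
  qs <- quat_random(3)
  means <- vapply(1:3, function(i) {
    sim <- simulate_trial(gait_sim_params(device_quat = qs[i, ]), seed = 55)
    analyze_trial(sim$trial)$metrics$stride_time_mean
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.002)
})
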