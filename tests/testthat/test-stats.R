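# brute-force oracles, independent of the package implementation
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# partial F for one added column, via explicit normal equations
anova_F_oracle <- function(y, X_red, x_add) {
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  X_full <- cbind(X_red, x_add)
  rss_r <- rss(X_red); rss_f <- rss(X_full)
  df2 <- length(y) - ncol(X_full)
  list(F = (rss_r - rss_f) / (rss_f / df2), df2 = df2)
}

test_that("validity handles the degenerate exact cases", {
  x <- c(1.0, 1.2, 1.4, 1.1, 1.3)
  v <- validity(x, x)
  expect_equal(v$pearson_r, 1)
  expect_equal(v$mean_abs_diff, 0)
  v2 <- validity(x, 2 * mean(x) - x)   # exact negation around the mean
  expect_equal(v2$pearson_r, -1)
  expect_error(validity(x, rep(1, 5)), "zero variance")
  expect_error(validity(x[1:2], x[1:2]), "at least 3")
  expect_error(validity(x, x[-1]), "matched")
})

test_that("validity equals the brute-force Pearson formula", {
  set.seed(19)
  for (rep in 1:10) {
    x <- rnorm(30); y <- 0.6 * x + rnorm(30)
    expect_equal(validity(x, y)$pearson_r, pearson_oracle(x, y),
                 tolerance = 1e-12)
  }
})

make_long <- function(n = 40, shift = 0.08, seed = 7) {
  set.seed(seed)
  base <- rnorm(n, 1.09, 0.08)
  data.frame(
    participant_id = rep(sprintf("P%02d", 1:n), 2),
    condition = rep(c("single_task", "dual_task"), each = n),
    stride_time_mean = c(base, base + shift + rnorm(n, 0, 0.05)),
    age = rep(round(rnorm(n, 63, 10)), 2),
    sex = rep(sample(c("male", "female"), n, TRUE), 2),
    education_years = rep(round(rnorm(n, 11, 3)), 2))
}

test_that("condition ANOVA F equals the nested sum-of-squares oracle", {
  d <- make_long()
  res <- condition_anova(d, "stride_time_mean")
  X_red <- cbind(1, d$age, as.numeric(d$sex == "male"), d$education_years)
  orc <- anova_F_oracle(d$stride_time_mean, X_red,
                        as.numeric(d$condition == "dual_task"))
  expect_equal(res$F_stat, orc$F, tolerance = 1e-9)
  expect_identical(res$df1, 1L)
  expect_equal(res$df2, orc$df2)
  expect_gt(res$beta_std, 0)  # dual > single
  expect_lt(res$p_value, 0.001)
})

test_that("a condition-free metric yields F near zero and p near one", {
  d <- make_long(shift = 0)
  d$stride_time_mean <- rep(d$stride_time_mean[1:40], 2)  # identical per participant
  res <- condition_anova(d, "stride_time_mean")
  expect_lt(res$F_stat, 1e-6)
  expect_gt(res$p_value, 0.999)
})

test_that("condition ANOVA validates its inputs", {
  d <- make_long()
  expect_error(condition_anova(d[, -4], "stride_time_mean"), "missing columns")
  expect_error(condition_anova(d[d$condition == "single_task", ],
                               "stride_time_mean"), "both task conditions")
})

test_that("standardized beta is invariant to affine rescaling", {
  set.seed(23)
  n <- 60
  co <- data.frame(metric = rnorm(n), age = rnorm(n, 63, 10),
                   sex = sample(c("male", "female"), n, TRUE),
                   education_years = rnorm(n, 11, 3))
  co$score <- 0.4 * co$metric + rnorm(n)
  b0 <- adjusted_association(co, "metric", "score")$beta_std
  co$metric <- 1000 * co$metric + 7
  co$score <- -0.01 * co$score + 3
  b1 <- adjusted_association(co, "metric", "score")$beta_std
  expect_equal(abs(b1), abs(b0), tolerance = 1e-9)
  expect_equal(sign(b1), -sign(b0))
})

test_that("adjusted association drops incomplete rows and reports counts", {
  set.seed(29)
  n <- 30
  co <- data.frame(metric = rnorm(n), score = rnorm(n),
                   age = rnorm(n, 63, 10),
                   sex = sample(c("male", "female"), n, TRUE),
                   education_years = rnorm(n, 11, 3))
  co$score[c(3, 9)] <- NA
  res <- adjusted_association(co, "metric", "score")
  expect_identical(res$n_used, 28L)
  expect_identical(res$n_dropped, 2L)
  co$metric <- 1
  expect_error(adjusted_association(co, "metric", "score"), "constant")
})

test_that("severity effects propagate in the clinically expected direction", {
  sim <- simulate_cohort(n_participants = 80, seed = 51, n_trials = 0)
  co <- sim$cohort
  co$variability_pct <- 100 * co$stride_cv_single
  res <- adjusted_association(co, "variability_pct", "updrs3")
  expect_gt(res$beta_std, 0.1)   # more variable gait, more severe disease
  res_m <- adjusted_association(co, "variability_pct", "moca")
  expect_lt(res_m$beta_std, -0.1)
})
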