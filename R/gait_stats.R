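# Study-level statistics: Pearson validity against a reference system,
# absolute differences, covariate-adjusted condition ANOVA on stacked
# participant-condition rows, and standardized-coefficient regressions of
# clinical scores on gait metrics.

DEFAULT_COVARIATES <- c("age", "sex", "education_years")

#' Criterion validity of a gait metric against a reference system
#'
#' Pearson correlation (two-sided p) between matched per-trial or
#' per-participant values from the pipeline and a reference, plus the mean
#' and SD of the absolute differences.
#'
#' @param app_values,ref_values Matched numeric vectors (length >= 3).
#' @param metric,condition Labels carried into the result.
#' @return Object of class `validity_result`: `metric`, `condition`,
#'   `pearson_r`, `p_value`, `mean_abs_diff`, `sd_abs_diff`, `n`.
#' @export
validity <- function(app_values, ref_values, metric = "metric",
                     condition = "all") {
  app_values <- as.numeric(app_values); ref_values <- as.numeric(ref_values)
  if (length(app_values) != length(ref_values)) {
    stop("app and reference vectors must be matched (equal length)")
  }
  ok <- is.finite(app_values) & is.finite(ref_values)
  app_values <- app_values[ok]; ref_values <- ref_values[ok]
  if (length(app_values) < 3L) stop("need at least 3 matched pairs")
  if (stats::sd(app_values) == 0 || stats::sd(ref_values) == 0) {
    stop("correlation undefined: zero variance in one of the vectors")
  }
  ct <- stats::cor.test(app_values, ref_values, method = "pearson")
  d <- abs(app_values - ref_values)
  structure(list(metric = metric, condition = condition,
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 mean_abs_diff = mean(d), sd_abs_diff = stats::sd(d),
                 n = length(d)),
            class = "validity_result")
}

#' @export
print.validity_result <- function(x, ...) {
  cat(sprintf("<validity> %s [%s]: r = %.3f (p = %.3g), |diff| = %.4f (SD %.4f), n = %d\n",
              x$metric, x$condition, x$pearson_r, x$p_value, x$mean_abs_diff,
              x$sd_abs_diff, x$n))
  invisible(x)
}

model_result <- function(outcome, predictor, beta_std = NA_real_,
                         se = NA_real_, F_stat = NA_real_, df1 = NA_integer_,
                         df2 = NA_integer_, p_value = NA_real_,
                         covariates = character(0), n_used = NA_integer_,
                         n_dropped = 0L) {
  structure(list(outcome = outcome, predictor = predictor,
                 beta_std = beta_std, se = se, F_stat = F_stat,
                 df1 = df1, df2 = df2, p_value = p_value,
                 covariates = covariates, n_used = n_used,
                 n_dropped = n_dropped),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s ~ %s (+ %s)\n", x$outcome, x$predictor,
              paste(x$covariates, collapse = " + ")))
  if (is.finite(x$F_stat)) {
    cat(sprintf("  F(%d, %d) = %.2f, p = %.3g\n", x$df1, x$df2, x$F_stat,
                x$p_value))
  }
  if (is.finite(x$beta_std)) {
    cat(sprintf("  standardized beta = %.3f (SE %.3f), p = %.3g, n = %d\n",
                x$beta_std, x$se, x$p_value, x$n_used))
  }
  invisible(x)
}

#' Covariate-adjusted effect of task condition on a gait metric
#'
#' Linear model `metric ~ condition + age + sex + education` on stacked
#' participant-condition rows; the F statistic for the condition term is the
#' nested-model (with/without condition) comparison.
#'
#' @param data Long data.frame: one row per participant-condition with the
#'   metric column, a `condition` column (`single_task`/`dual_task`) and the
#'   covariates.
#' @param metric Name of the metric column.
#' @param covariates Covariate column names.
#' @return A `model_result`; `beta_std` here holds the raw dual-minus-single
#'   adjusted difference (metric units), and `F_stat`/`df1`/`df2`/`p_value`
#'   the condition term test.
#' @export
condition_anova <- function(data, metric,
                            covariates = DEFAULT_COVARIATES) {
  miss <- setdiff(c(metric, "condition", covariates), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, c(metric, "condition", covariates)]), ]
  data$condition <- factor(data$condition, levels = CONDITIONS)
  if (nlevels(droplevels(data$condition)) < 2L) {
    stop("both task conditions must be present")
  }
  rhs <- paste(covariates, collapse = " + ")
  full <- stats::lm(stats::reformulate(c("condition", covariates),
                                       response = metric), data = data)
  reduced <- stats::lm(stats::reformulate(covariates, response = metric),
                       data = data)
  cmp <- stats::anova(reduced, full)
  model_result(outcome = metric, predictor = "condition",
               beta_std = unname(stats::coef(full)["conditiondual_task"]),
               F_stat = cmp$F[2], df1 = as.integer(cmp$Df[2]),
               df2 = as.integer(cmp$Res.Df[2]),
               p_value = cmp$`Pr(>F)`[2], covariates = covariates,
               n_used = nrow(data))
}

#' Covariate-adjusted association between a gait metric and a clinical score
#'
#' Fits `score ~ metric + age + sex + education` with the score and the
#' metric z-scored (covariates raw), so the metric coefficient is a
#' standardized beta. Rows with missing values are dropped and counted.
#'
#' @param cohort Per-participant data.frame.
#' @param gait_metric,clinical_score Column names.
#' @param covariates Covariate column names.
#' @return A `model_result` with `beta_std`, `se`, `p_value`, `n_used`,
#'   `n_dropped`.
#' @export
adjusted_association <- function(cohort, gait_metric, clinical_score,
                                 covariates = DEFAULT_COVARIATES) {
  miss <- setdiff(c(gait_metric, clinical_score, covariates), names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cols <- c(gait_metric, clinical_score, covariates)
  cc <- stats::complete.cases(cohort[, cols])
  n_dropped <- sum(!cc)
  d <- cohort[cc, cols]
  if (nrow(d) < 10L) stop("need at least 10 complete rows")
  if (stats::sd(d[[gait_metric]]) == 0) {
    stop("gait metric is constant; standardized beta undefined")
  }
  d$.score_z <- as.numeric(scale(d[[clinical_score]]))
  d$.metric_z <- as.numeric(scale(d[[gait_metric]]))
  fit <- stats::lm(stats::reformulate(c(".metric_z", covariates),
                                      response = ".score_z"), data = d)
  sm <- summary(fit)$coefficients
  model_result(outcome = clinical_score, predictor = gait_metric,
               beta_std = sm[".metric_z", "Estimate"],
               se = sm[".metric_z", "Std. Error"],
               p_value = sm[".metric_z", "Pr(>|t|)"],
               covariates = covariates, n_used = nrow(d),
               n_dropped = n_dropped)
}
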