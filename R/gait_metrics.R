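# Stride-time metrics: stride series from heel strikes, per-trial summary
# (mean, SD, coefficient-of-variation variability), dual-task cost, and
# per-participant aggregation across repeated trials.

#' Construct a per-trial gait metrics record
#'
#' @param trial_id,condition Trial identity.
#' @param n_strides Number of retained strides.
#' @param stride_time_mean,stride_time_sd Seconds. May be `NA` when
#'   `n_strides < 2`.
#' @param flags Character vector of quality warnings.
#' @return Object of class `metrics_record`; `stride_time_variability` is
#'   `100 * SD / mean` in percent.
#' @export
metrics_record <- function(trial_id, condition, n_strides, stride_time_mean,
                           stride_time_sd, flags = character(0)) {
  if (n_strides < 0) stop("n_strides must be non-negative")
  if (n_strides >= 2 && (!is.finite(stride_time_mean) || stride_time_mean <= 0)) {
    stop("stride_time_mean must be positive when n_strides >= 2")
  }
  variability <- if (is.finite(stride_time_mean) && stride_time_mean > 0) {
    100 * stride_time_sd / stride_time_mean
  } else {
    NA_real_
  }
  structure(list(trial_id = trial_id, condition = condition,
                 n_strides = as.integer(n_strides),
                 stride_time_mean = stride_time_mean,
                 stride_time_sd = stride_time_sd,
                 stride_time_variability = variability,
                 flags = flags),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> %s [%s]: %d strides, mean %.3f s, SD %.3f s, CV %.2f%%\n",
              x$trial_id, x$condition, x$n_strides, x$stride_time_mean,
              x$stride_time_sd, x$stride_time_variability))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Stride times from detected gait events
#'
#' Successive differences of heel-strike times within each straight-walking
#' segment; differences never span a removed turn. Strides outside the
#' physiological gate are flagged and dropped.
#'
#' @param events A `gait_events` object.
#' @param min_s,max_s Physiological stride-duration gate (s).
#' @return Object of class `stride_series`: `stride_times`, `n_dropped`,
#'   `flags`.
#' @export
stride_series <- function(events, min_s = 0.3, max_s = 3) {
  stopifnot(inherits(events, "gait_events"))
  st <- numeric(0)
  for (si in unique(events$heel_strike_segment)) {
    h <- events$heel_strikes[events$heel_strike_segment == si]
    if (length(h) >= 2L) st <- c(st, diff(h))
  }
  if (!length(st)) {
    stop("insufficient strides: fewer than 2 heel strikes in every segment")
  }
  ok <- st >= min_s & st <= max_s
  flags <- character(0)
  if (any(!ok)) flags <- "strides_out_of_range"
  structure(list(stride_times = st[ok], n_dropped = sum(!ok), flags = flags),
            class = "stride_series")
}

#' Summarize a stride series into a metrics record
#'
#' Mean stride time, sample (n-1) SD, and stride time variability — the
#' ratio of the SD of the stride times to the mean stride time, in percent.
#'
#' @param strides A `stride_series` (or bare numeric vector of stride times).
#' @param trial_id,condition Identity carried into the record.
#' @return A [metrics_record()].
#' @export
summarize_strides <- function(strides, trial_id = "trial",
                              condition = "single_task") {
  if (inherits(strides, "stride_series")) {
    st <- strides$stride_times
    flags <- strides$flags
  } else {
    st <- as.numeric(strides)
    flags <- character(0)
  }
  if (length(st) < 2L) stop("need at least 2 strides to summarize")
  if (length(st) < 5L) flags <- c(flags, "few_strides")
  metrics_record(trial_id = trial_id, condition = condition,
                 n_strides = length(st),
                 stride_time_mean = mean(st),
                 stride_time_sd = stats::sd(st),
                 flags = flags)
}

#' Dual-task cost of stride time and stride time variability
#'
#' Percent change of each metric from the single- to the dual-task condition:
#' `100 * (dual - single) / single`. Positive cost means worse dual-task
#' walking (longer or more variable strides).
#'
#' @param single,dual `metrics_record`s for the two conditions.
#' @return Object of class `dual_task_result` with the two records and
#'   `dtc_stride_time`, `dtc_variability` (percent).
#' @export
dual_task_cost <- function(single, dual) {
  stopifnot(inherits(single, "metrics_record"), inherits(dual, "metrics_record"))
  pct_change <- function(s, d) {
    if (!is.finite(s) || !is.finite(d)) {
      stop("dual-task cost undefined: single-task metric is zero or missing")
    }
    if (s == 0) {
      if (d == 0) return(0)  # no change at all: zero cost
      stop("dual-task cost undefined: single-task metric is zero or missing")
    }
    100 * (d - s) / s
  }
  structure(list(
    single = single, dual = dual,
    dtc_stride_time = pct_change(single$stride_time_mean,
                                 dual$stride_time_mean),
    dtc_variability = pct_change(single$stride_time_variability,
                                 dual$stride_time_variability)),
    class = "dual_task_result")
}

#' @export
print.dual_task_result <- function(x, ...) {
  cat(sprintf(
    "<dual_task_result> stride time %.3f -> %.3f s (DTC %.1f%%); variability %.2f -> %.2f%% (DTC %.1f%%)\n",
    x$single$stride_time_mean, x$dual$stride_time_mean, x$dtc_stride_time,
    x$single$stride_time_variability, x$dual$stride_time_variability,
    x$dtc_variability))
  invisible(x)
}

# elementwise mean of metrics_records (same condition assumed)
mean_record <- function(records) {
  r1 <- records[[1]]
  m <- mean(vapply(records, function(r) r$stride_time_mean, numeric(1)))
  s <- mean(vapply(records, function(r) r$stride_time_sd, numeric(1)))
  rec <- metrics_record(
    trial_id = paste(vapply(records, function(r) r$trial_id, character(1)),
                     collapse = "+"),
    condition = r1$condition,
    n_strides = round(mean(vapply(records, function(r) r$n_strides, numeric(1)))),
    stride_time_mean = m, stride_time_sd = s,
    flags = unique(unlist(lapply(records, function(r) r$flags))))
  # variability averaged across trials, not recomputed from averaged moments
  rec$stride_time_variability <-
    mean(vapply(records, function(r) r$stride_time_variability, numeric(1)))
  rec
}

#' Average dual-task results across a participant's repeated trials
#'
#' Elementwise arithmetic mean of all metrics; the dual-task costs are the
#' mean of the per-trial costs (not the cost of the averaged metrics).
#'
#' @param results List of 1-2 `dual_task_result`s for one participant.
#' @return A single `dual_task_result`.
#' @export
aggregate_participant <- function(results) {
  if (!length(results)) stop("no dual-task results to aggregate")
  stopifnot(all(vapply(results, inherits, logical(1), "dual_task_result")))
  if (length(results) == 1L) return(results[[1]])
  out <- structure(list(
    single = mean_record(lapply(results, `[[`, "single")),
    dual = mean_record(lapply(results, `[[`, "dual")),
    dtc_stride_time = mean(vapply(results, `[[`, numeric(1), "dtc_stride_time")),
    dtc_variability = mean(vapply(results, `[[`, numeric(1), "dtc_variability"))),
    class = "dual_task_result")
  out
}
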