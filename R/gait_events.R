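# Turn removal and gait-event detection. 180-degree turns are located by
# integrating the Earth-frame vertical angular rate in a sliding window;
# heel strikes and toe-offs of the phone-side leg are the trough nadirs
# following the relatively high and relatively low peaks of the filtered
# vertical acceleration, which alternate step by step.

#' Detect turning intervals from the vertical angular rate
#'
#' A turn is declared wherever the yaw angle accumulated inside a sliding
#' window reaches the threshold; candidate regions are refined to the span
#' where the (briefly smoothed) vertical rate exceeds 10% of its regional
#' peak, and near-adjacent intervals are merged.
#'
#' @param sig An `earth_frame_signal` (unfiltered gyro is fine and preferred).
#' @param window_s Sliding integration window (s).
#' @param yaw_threshold_deg Accumulated-yaw threshold (deg); below 180 so
#'   imperfect turns are still caught.
#' @param merge_gap_s Intervals closer than this are merged (s).
#' @return data.frame with columns `t_start`, `t_end`, `yaw_change_deg`
#'   (possibly 0 rows).
#' @export
detect_turns <- function(sig, window_s = 4, yaw_threshold_deg = 120,
                         merge_gap_s = 0.5) {
  stopifnot(inherits(sig, "earth_frame_signal"))
  gz <- sig$gyro[, 3]
  t <- sig$t
  n <- length(t)
  fs <- sig$fs
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      yaw_change_deg = numeric(0))
  yaw <- c(0, cumsum((gz[-1] + gz[-n]) / 2)) / fs  # cumulative yaw, rad
  W <- min(n - 1L, as.integer(round(window_s * fs)))
  thr <- yaw_threshold_deg * pi / 180
  d <- abs(yaw[(W + 1L):n] - yaw[1:(n - W)])
  hit <- which(d >= thr)
  if (!length(hit)) return(empty)
  # union of triggered windows -> coarse regions
  mask <- logical(n)
  for (run in split(hit, cumsum(c(1L, diff(hit) > 1L)))) {
    mask[run[1]:(run[length(run)] + W)] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # short moving average to suppress sensor noise before edge refinement
  k <- max(1L, as.integer(round(0.25 * fs)))
  gzs <- as.numeric(stats::filter(gz, rep(1 / k, k), sides = 2))
  gzs[is.na(gzs)] <- 0
  out <- empty
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    seg <- abs(gzs[s:e])
    rthr <- 0.1 * max(seg)
    above <- which(seg >= rthr)
    i1 <- s + above[1] - 1L
    i2 <- s + above[length(above)] - 1L
    out <- rbind(out, data.frame(
      t_start = t[i1], t_end = t[i2],
      yaw_change_deg = (yaw[i2] - yaw[i1]) * 180 / pi))
  }
  # merge intervals separated by less than merge_gap_s
  if (nrow(out) > 1L) {
    keep <- out[1, ]
    for (i in 2:nrow(out)) {
      last <- nrow(keep)
      if (out$t_start[i] - keep$t_end[last] < merge_gap_s) {
        keep$t_end[last] <- out$t_end[i]
        keep$yaw_change_deg[last] <- keep$yaw_change_deg[last] + out$yaw_change_deg[i]
      } else {
        keep <- rbind(keep, out[i, ])
      }
    }
    out <- keep
  }
  rownames(out) <- NULL
  out
}

#' Straight-walking segments: the trial span minus dilated turns
#'
#' @param sig An `earth_frame_signal` (supplies the trial span).
#' @param turns data.frame from [detect_turns()].
#' @param margin_s Dilation applied to each side of every turn (s); gait is
#'   unsteady entering and leaving a turn.
#' @param min_len_s Segments shorter than this are discarded (s).
#' @return data.frame with columns `t_start`, `t_end`.
#' @export
straight_segments <- function(sig, turns, margin_s = 0.5, min_len_s = 3) {
  stopifnot(inherits(sig, "earth_frame_signal"))
  lo <- sig$t[1]
  hi <- sig$t[length(sig$t)]
  if (is.null(turns) || nrow(turns) == 0L) {
    segs <- data.frame(t_start = lo, t_end = hi)
  } else {
    turns <- turns[order(turns$t_start), , drop = FALSE]
    cur <- lo
    segs <- data.frame(t_start = numeric(0), t_end = numeric(0))
    for (i in seq_len(nrow(turns))) {
      a <- turns$t_start[i] - margin_s
      b <- turns$t_end[i] + margin_s
      if (a > cur) segs <- rbind(segs, data.frame(t_start = cur, t_end = a))
      cur <- max(cur, b)
    }
    if (cur < hi) segs <- rbind(segs, data.frame(t_start = cur, t_end = hi))
  }
  segs <- segs[segs$t_end - segs$t_start >= min_len_s, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

# Topographic prominence of local maxima: height above the higher of the two
# key saddles (minimum between the peak and the nearest higher terrain on
# each side; the full side minimum when no higher terrain exists).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[1:(p - 1L)] else numeric(0)
    right <- if (p < length(x)) x[(p + 1L):length(x)] else numeric(0)
    lb <- if (length(left)) {
      higher <- which(left > h)
      if (length(higher)) min(left[(max(higher) + 1L):length(left)]) else min(left)
    } else h
    rb <- if (length(right)) {
      higher <- which(right > h)
      if (length(higher)) min(right[1:(min(higher) - 1L)]) else min(right)
    } else h
    h - max(lb, rb)
  }, numeric(1))
}

find_peaks <- function(x, min_spacing, min_prom_factor, fs,
                       iqr_window_s = 2, min_rel_amp = 0.25) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  w <- as.integer(round(iqr_window_s * fs))
  local_iqr <- vapply(cand, function(p) {
    stats::IQR(x[max(1L, p - w):min(n, p + w)])
  }, numeric(1))
  cand <- cand[prom >= min_prom_factor * local_iqr]
  if (!length(cand)) return(integer(0))
  # enforce minimum spacing, keeping taller peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_spacing)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  # reject residual low-amplitude artifacts (walk initiation/termination
  # ramps): genuine step peaks are a large fraction of the typical peak
  # height, even on the quieter (contralateral) side
  med <- stats::median(x[kept])
  if (is.finite(med) && med > 0) kept <- kept[x[kept] >= min_rel_amp * med]
  kept
}

# Classify peaks as relatively high / relatively low against the median of up
# to 4 surrounding peaks, then enforce strict high/low alternation by picking
# the alternating phase that best agrees with the amplitude scores.
classify_peaks <- function(amp) {
  K <- length(amp)
  if (K == 0L) return(character(0))
  score <- vapply(seq_len(K), function(j) {
    nb <- setdiff(max(1L, j - 2L):min(K, j + 2L), j)
    amp[j] - stats::median(amp[nb])
  }, numeric(1))
  if (K == 1L) return(if (score >= 0) "high" else "low")
  sgn_odd <- ifelse(seq_len(K) %% 2L == 1L, 1, -1)  # odd peaks high
  if (sum(score * sgn_odd) >= 0) {
    ifelse(sgn_odd > 0, "high", "low")
  } else {
    ifelse(sgn_odd > 0, "low", "high")
  }
}

# Parabolic (three-point) refinement of an extremum location, in samples.
refine_extremum <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(0)
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(0)
  delta <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  max(-0.5, min(0.5, delta))
}

#' Detect heel-strike and toe-off events of the phone-side leg
#'
#' Within each straight-walking segment, local maxima of the filtered
#' vertical acceleration are found (minimum prominence relative to a local
#' inter-quartile range; minimum spacing), classified as relatively high or
#' relatively low with strict alternation, and the trough nadir following
#' each high peak is taken as a heel strike, the trough following each low
#' peak as a toe-off. Events too close to segment boundaries are dropped.
#'
#' @param sig A filtered `earth_frame_signal`.
#' @param segments data.frame from [straight_segments()].
#' @param min_prominence_factor Prominence threshold as a fraction of the
#'   local IQR of the filtered vertical acceleration.
#' @param min_spacing_s Minimum separation between retained peaks (s);
#'   default 0.35 s sits above the physiological step-rate limit.
#' @param boundary_s Events within this margin of a segment edge are dropped.
#' @param refine Parabolic sub-sample refinement of trough times.
#' @return Object of class `gait_events`: `segments`, `peaks` (data.frame
#'   `segment`, `time`, `amplitude`, `class`), `heel_strikes`, `toe_offs`,
#'   `heel_strike_segment`, `toe_off_segment`.
#' @export
detect_gait_events <- function(sig, segments, min_prominence_factor = 0.3,
                               min_spacing_s = 0.35, boundary_s = 0.5,
                               refine = TRUE) {
  stopifnot(inherits(sig, "earth_frame_signal"))
  if (!isTRUE(sig$filtered)) {
    stop("detect_gait_events requires a low-pass filtered signal; call lowpass() first")
  }
  fs <- sig$fs
  spacing <- as.integer(round(min_spacing_s * fs))
  peaks_df <- data.frame(segment = integer(0), time = numeric(0),
                         amplitude = numeric(0), class = character(0))
  hs <- numeric(0); hs_seg <- integer(0)
  to <- numeric(0); to_seg <- integer(0)
  any_walkable <- FALSE
  for (si in seq_len(nrow(segments))) {
    idx <- which(sig$t >= segments$t_start[si] & sig$t <= segments$t_end[si])
    if (length(idx) < 3L) next
    x <- sig$acc[idx, 3]
    tt <- sig$t[idx]
    pk <- find_peaks(x, spacing, min_prominence_factor, fs)
    if (length(pk) < 4L) next
    any_walkable <- TRUE
    cls <- classify_peaks(x[pk])
    peaks_df <- rbind(peaks_df, data.frame(
      segment = si, time = tt[pk], amplitude = x[pk], class = cls))
    lo_t <- segments$t_start[si] + boundary_s
    hi_t <- segments$t_end[si] - boundary_s
    for (j in seq_along(pk)) {
      if (j == length(pk)) next  # trough must lie between consecutive peaks
      a <- pk[j]
      b <- pk[j + 1L]
      if (b - a < 2L) next
      w <- (a + 1L):(b - 1L)
      m <- w[which.min(x[w])]
      tm <- tt[m] + if (refine) refine_extremum(x, m) / fs else 0
      if (tm < lo_t || tm > hi_t) next
      if (cls[j] == "high") {
        hs <- c(hs, tm); hs_seg <- c(hs_seg, si)
      } else {
        to <- c(to, tm); to_seg <- c(to_seg, si)
      }
    }
  }
  if (!any_walkable) {
    stop("insufficient gait: fewer than 4 peaks detected in every straight-walking segment")
  }
  o <- order(hs)
  structure(list(segments = segments, peaks = peaks_df,
                 heel_strikes = hs[o], heel_strike_segment = hs_seg[o],
                 toe_offs = sort(to), toe_off_segment = to_seg[order(to)]),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d segment(s), %d peaks, %d heel strikes, %d toe-offs\n",
              nrow(x$segments), nrow(x$peaks), length(x$heel_strikes),
              length(x$toe_offs)))
  invisible(x)
}
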