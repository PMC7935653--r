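# Trial I/O: on-disk CSV format for raw pocket-IMU walking trials plus a JSON
# sidecar for free-form metadata, and JSON serialization of gait metrics.
#
# CSV header (fixed order): t,ax,ay,az,gx,gy,gz[,qw,qx,qy,qz][,heading]
# Units are SI: seconds from trial start, m/s^2, rad/s; quaternions are
# scalar-first device->Earth; heading in degrees.

CONDITIONS <- c("single_task", "dual_task")

#' Construct and validate a raw IMU walking trial
#'
#' @param trial_id Character scalar identifying the trial.
#' @param condition `"single_task"` or `"dual_task"`.
#' @param t Strictly increasing timestamps in seconds.
#' @param acc N x 3 accelerometer matrix, device frame, m/s^2.
#' @param gyro N x 3 gyroscope matrix, device frame, rad/s.
#' @param quat Optional N x 4 unit quaternions (scalar-first, device->Earth).
#' @param heading Optional compass heading per sample, degrees.
#' @param fs_nominal Nominal sampling rate in Hz (default 100).
#' @param meta Named list of free metadata (participant id, trial index, ...).
#' @param units Units of the supplied `acc`/`gyro`: `"si"` (default) or
#'   `"g_deg"` for g and deg/s, converted to SI on construction.
#' @return An object of class `imu_trial`. Quality warnings (irregular
#'   sampling, dropped samples) are recorded in `$flags`, not raised as errors.
#' @export
imu_trial <- function(trial_id, condition, t, acc, gyro, quat = NULL,
                      heading = NULL, fs_nominal = 100, meta = list(),
                      units = c("si", "g_deg")) {
  units <- match.arg(units)
  condition <- as.character(condition)
  if (!condition %in% CONDITIONS) {
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  }
  t <- as.numeric(t)
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  if (ncol(acc) != 3L || ncol(gyro) != 3L) stop("acc and gyro must have 3 columns")
  n <- length(t)
  if (nrow(acc) != n || nrow(gyro) != n) {
    stop("t, acc and gyro must have equal length")
  }
  if (n < 2L) stop("trial must contain at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (units == "g_deg") {
    acc <- acc * 9.80665
    gyro <- gyro * pi / 180
  }
  if (!is.null(quat)) {
    quat <- as.matrix(quat)
    if (nrow(quat) != n || ncol(quat) != 4L) stop("quat must be an N x 4 matrix")
    if (any(abs(sqrt(rowSums(quat^2)) - 1) > 1e-6)) {
      stop("quaternion rows must be unit-norm within 1e-6")
    }
  }
  if (!is.null(heading)) {
    heading <- as.numeric(heading)
    if (length(heading) != n) stop("heading length must match t")
  }
  med_dt <- stats::median(dt)
  if (abs(med_dt - 1 / fs_nominal) > 0.1 / fs_nominal) {
    stop(sprintf(
      "median sampling interval %.4f s deviates >10%% from nominal 1/%g s",
      med_dt, fs_nominal))
  }
  flags <- character(0)
  if (any(dt > 1.5 * med_dt)) flags <- c(flags, "irregular_sampling")
  n_expected <- (t[n] - t[1]) / med_dt + 1
  if ((n_expected - n) / n_expected > 0.05) flags <- c(flags, "dropped_samples")
  structure(list(trial_id = as.character(trial_id), condition = condition,
                 t = t, acc = unname(acc), gyro = unname(gyro),
                 quat = if (is.null(quat)) NULL else unname(quat),
                 heading = heading, fs_nominal = fs_nominal,
                 meta = meta, flags = flags),
            class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %s [%s]: %d samples, %.1f s @ %g Hz nominal%s\n",
              x$trial_id, x$condition, length(x$t), diff(range(x$t)),
              x$fs_nominal,
              if (is.null(x$quat)) "" else ", quaternions attached"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

trial_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Write an IMU trial to CSV (+ JSON metadata sidecar)
#'
#' Numeric columns are written at full precision so that
#' [read_trial()] reproduces the trial bit-identically.
#'
#' @param trial An [imu_trial()] object.
#' @param path Output CSV path; the sidecar goes to `<path minus ext>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "imu_trial"))
  cols <- list(t = trial$t,
               ax = trial$acc[, 1], ay = trial$acc[, 2], az = trial$acc[, 3],
               gx = trial$gyro[, 1], gy = trial$gyro[, 2], gz = trial$gyro[, 3])
  if (!is.null(trial$quat)) {
    cols$qw <- trial$quat[, 1]; cols$qx <- trial$quat[, 2]
    cols$qy <- trial$quat[, 3]; cols$qz <- trial$quat[, 4]
  }
  if (!is.null(trial$heading)) cols$heading <- trial$heading
  # 17 significant digits: doubles survive the text round trip bit-exactly
  df <- data.table::as.data.table(lapply(cols, function(x) sprintf("%.17g", x)))
  data.table::fwrite(df, path, quote = FALSE)
  sidecar <- list(trial_id = trial$trial_id, condition = trial$condition,
                  fs_nominal = trial$fs_nominal, meta = trial$meta)
  jsonlite::write_json(sidecar, trial_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and validate an IMU trial from CSV
#'
#' Expects the column layout written by [write_trial()]; `qw..qz` and
#' `heading` are optional. Metadata is taken from the JSON sidecar when
#' present, else from the `trial_id`/`condition` arguments.
#'
#' @param path CSV file path.
#' @param trial_id,condition,fs_nominal Fallbacks when no sidecar exists.
#' @return An [imu_trial()].
#' @export
read_trial <- function(path, trial_id = NULL, condition = "single_task",
                       fs_nominal = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path)
  required <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trial file is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  meta <- list()
  sc <- trial_sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    trial_id <- side$trial_id %||% trial_id
    condition <- side$condition %||% condition
    fs_nominal <- side$fs_nominal %||% fs_nominal
    meta <- as.list(side$meta %||% list())
  }
  if (is.null(trial_id)) trial_id <- tools::file_path_sans_ext(basename(path))
  quat <- NULL
  if (all(c("qw", "qx", "qy", "qz") %in% names(df))) {
    quat <- as.matrix(df[, c("qw", "qx", "qy", "qz"), with = FALSE])
  }
  heading <- if ("heading" %in% names(df)) df$heading else NULL
  imu_trial(trial_id = trial_id, condition = condition, t = df$t,
            acc = as.matrix(df[, c("ax", "ay", "az"), with = FALSE]),
            gyro = as.matrix(df[, c("gx", "gy", "gz"), with = FALSE]),
            quat = quat, heading = heading, fs_nominal = fs_nominal,
            meta = meta)
}

#' Serialize gait metric records to JSON (and optionally CSV)
#'
#' @param records A list of metric records as returned by
#'   [summarize_strides()] (each a `metrics_record`), or a single record.
#' @param path Output JSON path.
#' @param csv Optional CSV path for a flat table of the same records.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path, csv = NULL) {
  if (inherits(records, "metrics_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "metrics_record"))
    list(trial_id = r$trial_id, condition = r$condition,
         n_strides = r$n_strides,
         stride_time_mean_s = r$stride_time_mean,
         stride_time_sd_s = r$stride_time_sd,
         stride_time_variability_pct = r$stride_time_variability,
         flags = as.list(r$flags))
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(csv)) {
    flat <- data.table::rbindlist(lapply(rows, function(r) {
      r$flags <- paste(unlist(r$flags), collapse = ";")
      r
    }))
    data.table::fwrite(flat, csv)
  }
  invisible(path)
}

#' Read back gait metric records written by [write_metrics()]
#' @param path JSON file path.
#' @return List of `metrics_record` objects.
#' @export
read_metrics <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(rows, function(r) {
    metrics_record(trial_id = r$trial_id, condition = r$condition,
                   n_strides = r$n_strides,
                   stride_time_mean = r$stride_time_mean_s,
                   stride_time_sd = r$stride_time_sd_s,
                   flags = unlist(r$flags) %||% character(0))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
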