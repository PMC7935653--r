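# Device-frame -> Earth-frame preprocessing: attitude estimation when the
# phone supplies no quaternions, sample-wise quaternion rotation so the Z axis
# is vertical regardless of pocket orientation, gravity removal, uniform
# resampling, and zero-phase low-pass Butterworth filtering.

#' Estimate per-sample device-to-Earth attitude
#'
#' Complementary filter: tilt is anchored to the low-frequency accelerometer
#' gravity direction while the gyroscope is integrated for short-term
#' dynamics. Yaw is left arbitrary — downstream analysis only consumes the
#' vertical axis and the rotation rate about it. When the trial already
#' carries quaternions they are returned unchanged.
#'
#' @param trial An [imu_trial()].
#' @param tilt_cutoff_hz Cutoff of the accelerometer tilt anchor (Hz).
#'   The correction time constant is `1/(2*pi*tilt_cutoff_hz)`.
#' @param init_window_s Initial window averaged to seed the attitude (s).
#' @return N x 4 matrix of unit quaternions (scalar-first, device->Earth).
#' @export
estimate_orientation <- function(trial, tilt_cutoff_hz = 0.25,
                                 init_window_s = 0.5) {
  stopifnot(inherits(trial, "imu_trial"))
  if (!is.null(trial$quat)) return(trial$quat)
  t <- trial$t
  if (t[length(t)] - t[1] < 2) stop("need at least 2 s of data to estimate orientation")
  acc <- trial$acc; gyro <- trial$gyro
  norms <- sqrt(rowSums(acc^2))
  if (mean(norms) < 1) {
    stop("mean acceleration norm near zero (free-fall-like input); cannot estimate gravity direction")
  }
  tau <- 1 / (2 * pi * tilt_cutoff_hz)
  n <- length(t)
  a0 <- colMeans(acc[t <= t[1] + init_window_s, , drop = FALSE])
  q <- quat_between(a0, c(0, 0, 1))
  out <- matrix(0, n, 4)
  out[1, ] <- q
  qw <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  for (k in 2:n) {
    dt <- t[k] - t[k - 1]
    # gyro propagation (body-frame rate, midpoint rule): q <- q * dq
    wx <- (gyro[k - 1, 1] + gyro[k, 1]) * 0.5 * dt
    wy <- (gyro[k - 1, 2] + gyro[k, 2]) * 0.5 * dt
    wz <- (gyro[k - 1, 3] + gyro[k, 3]) * 0.5 * dt
    ang <- sqrt(wx * wx + wy * wy + wz * wz)
    if (ang > 0) {
      s <- sin(ang / 2) / ang
      dw <- cos(ang / 2); dx <- wx * s; dy <- wy * s; dz <- wz * s
      nw <- qw * dw - qx * dx - qy * dy - qz * dz
      nx <- qw * dx + qx * dw + qy * dz - qz * dy
      ny <- qw * dy - qx * dz + qy * dw + qz * dx
      nz <- qw * dz + qx * dy - qy * dx + qz * dw
      qw <- nw; qx <- nx; qy <- ny; qz <- nz
    }
    # accelerometer tilt correction (Earth frame, small slerp fraction)
    an <- sqrt(acc[k, 1]^2 + acc[k, 2]^2 + acc[k, 3]^2)
    if (an > 1e-6) {
      vx <- acc[k, 1] / an; vy <- acc[k, 2] / an; vz <- acc[k, 3] / an
      # measured up direction rotated into Earth frame: u = q v q*
      tx <- 2 * (qy * vz - qz * vy)
      ty <- 2 * (qz * vx - qx * vz)
      tz <- 2 * (qx * vy - qy * vx)
      ux <- vx + qw * tx + (qy * tz - qz * ty)
      uy <- vy + qw * ty + (qz * tx - qx * tz)
      uz <- vz + qw * tz + (qx * ty - qy * tx)
      # rotation from u to e_z: axis = u x e_z = (uy, -ux, 0)
      sn <- sqrt(ux * ux + uy * uy)
      if (sn > 1e-12) {
        err <- atan2(sn, uz)
        alpha <- dt / (tau + dt)
        half <- 0.5 * alpha * err
        cw <- cos(half); cs <- sin(half) / sn
        cx <- uy * cs; cy <- -ux * cs
        nw <- cw * qw - cx * qx - cy * qy
        nx <- cw * qx + cx * qw + cy * qz
        ny <- cw * qy - cx * qz + cy * qw
        nz <- cw * qz + cx * qy - cy * qx
        qw <- nw; qx <- nx; qy <- ny; qz <- nz
      }
    }
    nrm <- sqrt(qw * qw + qx * qx + qy * qy + qz * qz)
    qw <- qw / nrm; qx <- qx / nrm; qy <- qy / nrm; qz <- qz / nrm
    out[k, 1] <- qw; out[k, 2] <- qx; out[k, 3] <- qy; out[k, 4] <- qz
  }
  out
}

#' Rotate a trial into the Earth frame and remove gravity
#'
#' Signals are resampled to a uniform rate by linear interpolation, rotated
#' sample-wise by the supplied quaternions so that Z is approximately
#' vertical, and the scalar gravity magnitude is subtracted from the rotated
#' vertical acceleration. The rotation is an isometry: per-sample vector
#' norms are preserved before gravity removal.
#'
#' @param trial An [imu_trial()].
#' @param quat N x 4 quaternion matrix matching the trial samples
#'   (e.g. from [estimate_orientation()]).
#' @param fs Target uniform rate (Hz); default the trial's nominal rate.
#' @param g Gravity magnitude subtracted from the vertical axis (m/s^2).
#' @return An object of class `earth_frame_signal` with fields `t`, `acc`,
#'   `gyro`, `fs`, `filtered`, `cutoff`, `g`.
#' @export
rotate_to_earth <- function(trial, quat, fs = NULL, g = 9.81) {
  stopifnot(inherits(trial, "imu_trial"))
  quat <- as.matrix(quat)
  if (nrow(quat) != length(trial$t) || ncol(quat) != 4L) {
    stop("quat must be an N x 4 matrix matching the trial length")
  }
  fs <- fs %||% trial$fs_nominal
  t0 <- trial$t
  tu <- seq(t0[1], t0[length(t0)], by = 1 / fs)
  interp_cols <- function(m) {
    vapply(seq_len(ncol(m)),
           function(j) stats::approx(t0, m[, j], xout = tu)$y,
           numeric(length(tu)))
  }
  acc_u <- interp_cols(trial$acc)
  gyro_u <- interp_cols(trial$gyro)
  quat_u <- quat_normalize(interp_cols(quat))
  acc_e <- quat_rotate(quat_u, acc_u)
  gyro_e <- quat_rotate(quat_u, gyro_u)
  acc_e[, 3] <- acc_e[, 3] - g
  structure(list(t = tu, acc = acc_e, gyro = gyro_e, fs = fs,
                 filtered = FALSE, cutoff = NA_real_, g = g),
            class = "earth_frame_signal")
}

#' @export
print.earth_frame_signal <- function(x, ...) {
  cat(sprintf("<earth_frame_signal> %d samples @ %g Hz, %s\n",
              length(x$t), x$fs,
              if (x$filtered) sprintf("low-pass filtered at %g Hz", x$cutoff)
              else "unfiltered"))
  invisible(x)
}

# Forward-backward Butterworth pass with odd-reflection end padding to keep
# edge transients out of the analysis span. Zero phase: peak/trough timing is
# not lag-biased, which matters because timing is the measurand.
zero_phase_butter <- function(x, fs, cutoff, order) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  L <- min(n - 1L, as.integer(round(6 * fs / cutoff)))
  xp <- c(2 * x[1] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
  # remove the edge offset before each pass: the zero-state transient then
  # acts on a signal starting at 0 (unit DC gain restores the offset)
  yf <- as.numeric(signal::filter(bf, xp - xp[1])) + xp[1]
  z <- rev(yf)
  yb <- rev(as.numeric(signal::filter(bf, z - z[1])) + z[1])
  yb[(L + 1L):(L + n)]
}

#' Zero-phase low-pass Butterworth filter of an Earth-frame signal
#'
#' All six channels are filtered forward and backward (squared magnitude
#' response, zero phase lag).
#'
#' @param sig An `earth_frame_signal`.
#' @param cutoff Cutoff frequency in Hz (default 3).
#' @param order Butterworth order of each pass (default 4).
#' @return The filtered `earth_frame_signal` (`filtered = TRUE`).
#' @export
lowpass <- function(sig, cutoff = 3, order = 4) {
  stopifnot(inherits(sig, "earth_frame_signal"))
  if (sig$fs <= 2 * cutoff) {
    stop(sprintf("sampling rate %g Hz must exceed twice the cutoff %g Hz",
                 sig$fs, cutoff))
  }
  for (j in 1:3) {
    sig$acc[, j] <- zero_phase_butter(sig$acc[, j], sig$fs, cutoff, order)
    sig$gyro[, j] <- zero_phase_butter(sig$gyro[, j], sig$fs, cutoff, order)
  }
  sig$filtered <- TRUE
  sig$cutoff <- cutoff
  sig
}
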