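# Quaternion algebra for device->Earth attitude handling.
# Convention throughout the package: scalar-first (w, x, y, z), unit
# quaternions, right-handed frames; q rotates device-frame vectors into the
# Earth frame via v_earth = q (0, v) q*.

#' Normalize quaternions to unit norm
#'
#' @param q Numeric vector of length 4 or an N x 4 matrix (scalar-first).
#' @return Object of the same shape with each quaternion scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  if (is.null(dim(q))) {
    n <- sqrt(sum(q^2))
    if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
    return(q / n)
  }
  n <- sqrt(rowSums(q^2))
  if (any(n < .Machine$double.eps)) stop("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternion sets
#'
#' Either argument may be a single quaternion (length-4 vector) or an N x 4
#' matrix; single quaternions are recycled.
#'
#' @param a,b Quaternions, scalar-first.
#' @return N x 4 matrix (or length-4 vector when both inputs are vectors).
#' @export
quat_multiply <- function(a, b) {
  va <- is.null(dim(a)); vb <- is.null(dim(b))
  if (va) a <- matrix(a, nrow = 1)
  if (vb) b <- matrix(b, nrow = 1)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  if (va && vb) out[1, ] else out
}

#' Quaternion conjugate
#' @param q Length-4 vector or N x 4 matrix.
#' @return Same shape, vector part negated.
#' @export
quat_conjugate <- function(q) {
  if (is.null(dim(q))) return(c(q[1], -q[2], -q[3], -q[4]))
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
}

#' Rotate 3-vectors by quaternions
#'
#' Applies v' = q (0, v) q* sample-wise. `q` may be one quaternion applied to
#' all rows of `v`, or one quaternion per row.
#'
#' @param q Length-4 vector or N x 4 matrix, unit norm.
#' @param v Length-3 vector or N x 3 matrix.
#' @return Rotated vectors, same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  vv <- is.null(dim(v))
  if (vv) v <- matrix(v, nrow = 1)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  qw <- q[, 1]; qx <- q[, 2]; qy <- q[, 3]; qz <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 * (q_vec x v)
  tx <- 2 * (qy * vz - qz * vy)
  ty <- 2 * (qz * vx - qx * vz)
  tz <- 2 * (qx * vy - qy * vx)
  out <- cbind(vx + qw * tx + (qy * tz - qz * ty),
               vy + qw * ty + (qz * tx - qx * tz),
               vz + qw * tz + (qx * ty - qy * tx),
               deparse.level = 0)
  if (vv) out[1, ] else out
}

#' Quaternion from rotation axis and angle
#' @param axis Length-3 axis (need not be unit).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion, scalar-first.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Minimal rotation taking one direction onto another
#'
#' Returns the quaternion of smallest angle q such that rotating `u` gives a
#' vector parallel to `v` (both are normalized internally).
#'
#' @param u,v Length-3 vectors.
#' @return Unit quaternion.
#' @export
quat_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to u
    ax <- c(1, 0, 0)
    if (abs(u[1]) > 0.9) ax <- c(0, 1, 0)
    ax <- ax - sum(ax * u) * u
    return(quat_from_axis_angle(ax, pi))
  }
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  quat_normalize(c(1 + d, cr))
}

#' Draw uniformly random unit quaternions
#' @param n Number of quaternions.
#' @return N x 4 matrix of unit quaternions (uses the current RNG stream).
#' @export
quat_random <- function(n = 1L) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  quat_normalize(m)
}

# Rotation about Earth Z by yaw angle psi (radians); vectorized over psi.
quat_yaw <- function(psi) {
  cbind(cos(psi / 2), 0, 0, sin(psi / 2), deparse.level = 0)
}
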