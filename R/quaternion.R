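# Quaternion utilities.
#
# Convention throughout the package: unit quaternions are rows of an n x 4
# matrix with columns (w, x, y, z), scalar first. A quaternion q maps vectors
# from the sensor/body frame to the world frame: v_world = q (x) v_body (x) q*.
# World frame: z up, x = magnetic-north horizontal, right handed.

#' Quaternion utilities
#'
#' Quaternions are rows of an n x 4 matrix, scalar first (w, x, y, z),
#' mapping sensor/body coordinates to world coordinates. These helpers are
#' exported so that orientation tracks and segment frames can be manipulated
#' directly.
#'
#' @param w,x,y,z numeric vectors (recycled to a common length).
#' @return `quat()` returns an n x 4 quaternion matrix.
#' @export
quat <- function(w, x = 0, y = 0, z = 0) {
  m <- cbind(w = w, x = x, y = y, z = z)
  storage.mode(m) <- "double"
  m
}

q_identity <- function(n = 1) quat(rep(1, n), 0, 0, 0)

#' @rdname quat
#' @param q,a,b n x 4 quaternion matrices (single rows are recycled).
#' @export
q_normalize <- function(q) {
  q <- rbind(q)
  n <- sqrt(rowSums(q^2))
  q / n
}

#' @rdname quat
#' @export
q_conj <- function(q) {
  q <- rbind(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' @rdname quat
#' @export
q_mult <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z)
}

#' @rdname quat
#' @param v n x 3 matrix of body-frame vectors (or a single row recycled).
#' @export
q_rotate <- function(q, v) {
  q <- rbind(q); v <- rbind(v)
  if (nrow(q) == 1 && nrow(v) > 1) q <- q[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(q) > 1) v <- v[rep(1, nrow(q)), , drop = FALSE]
  # v' = v + 2 q_w (q_v x v) + 2 q_v x (q_v x v)
  qv <- q[, 2:4, drop = FALSE]
  t1 <- 2 * cross3(qv, v)
  v + q[, 1] * t1 + cross3(qv, t1)
}

cross3 <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @rdname quat
#' @param rv n x 3 matrix of rotation vectors, radians.
#' @export
q_from_rotvec <- function(rv) {
  rv <- rbind(rv)
  ang <- sqrt(rowSums(rv^2))
  half <- ang / 2
  # sinc(half) guarded near zero
  k <- ifelse(ang < 1e-12, 0.5, sin(half) / ang)
  cbind(cos(half), rv[, 1] * k, rv[, 2] * k, rv[, 3] * k)
}

#' @rdname quat
#' @export
q_to_rotvec <- function(q) {
  q <- rbind(q)
  # force w >= 0 so the angle lies in [0, pi]
  s <- ifelse(q[, 1] < 0, -1, 1)
  q <- q * s
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, q[, 1])
  k <- ifelse(vn < 1e-12, 2, ang / vn)
  q[, 2:4, drop = FALSE] * k
}

#' @rdname quat
#' @param axis unit 3-vector (rows recycled against `angle_rad`).
#' @param angle_rad rotation angles, radians.
#' @export
q_from_axis_angle <- function(axis, angle_rad) {
  axis <- rbind(axis)
  axis <- axis / sqrt(rowSums(axis^2))
  if (nrow(axis) == 1 && length(angle_rad) > 1)
    axis <- axis[rep(1, length(angle_rad)), , drop = FALSE]
  q_from_rotvec(axis * angle_rad)
}

#' @rdname quat
#' @export
q_angle <- function(q) {
  q <- rbind(q)
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  2 * atan2(vn, abs(q[, 1]))
}

#' Enforce a continuous sign convention along a quaternion track
#' @keywords internal
q_fix_sign <- function(q) {
  q <- rbind(q)
  if (nrow(q) < 2) return(q)
  d <- rowSums(q[-1, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flip <- cumprod(ifelse(d < 0, -1, 1))
  q[-1, ] <- q[-1, , drop = FALSE] * flip
  q
}

#' Chordal mean of a set of unit quaternions (largest-eigenvector method)
#' @keywords internal
q_mean <- function(q) {
  q <- rbind(q)
  if (nrow(q) == 1) return(q_normalize(q))
  M <- crossprod(q) / nrow(q)
  ev <- eigen(M, symmetric = TRUE)
  m <- ev$vectors[, 1]
  if (m[1] < 0) m <- -m
  q_normalize(matrix(m, 1))
}

quat_to_rotmat <- function(q) {
  q <- q_normalize(rbind(q))
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q_normalize(matrix(q, 1))
}

#' Static orientation from an accelerometer and magnetometer reading
#'
#' TRIAD-style construction: the accelerometer fixes world "up" in the body
#' frame (specific force points up when static), the magnetometer fixes the
#' horizontal heading. Returns the body->world quaternion.
#' @keywords internal
q_from_acc_mag <- function(acc, mag) {
  zb <- acc / sqrt(sum(acc^2))            # world z expressed in body frame
  m <- mag / sqrt(sum(mag^2))
  eb <- cross3(m, zb)                     # world east-ish = north x ... sign below
  eb <- eb / sqrt(sum(eb^2))
  # world axes in body coords: x = north (horizontal), y = z x x, z = up
  xb <- cross3(zb, eb)                    # horizontal north component
  xb <- xb / sqrt(sum(xb^2))
  yb <- cross3(rbind(zb), xb)
  # rows of R (body->world) are the world axes expressed in body coordinates
  R <- rbind(as.numeric(xb), as.numeric(yb), as.numeric(zb))
  rotmat_to_quat(R)
}

#' Relative angular velocity between two quaternion samples
#'
#' Body-frame angular rate over [t_k, t_k+1] such that
#' q_{k+1} = q_k (x) exp(omega * dt). Used both to synthesise gyro signals and
#' to integrate them back, so the two operations are exact inverses.
#' @keywords internal
q_body_rates <- function(q, dt) {
  q <- rbind(q)
  n <- nrow(q)
  if (n < 2) return(matrix(0, n, 3))
  dq <- q_mult(q_conj(q[-n, , drop = FALSE]), q[-1, , drop = FALSE])
  w <- q_to_rotvec(dq) / dt
  rbind(w, w[nrow(w), , drop = FALSE])    # repeat last to keep length n
}
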