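# Joint kinematics: knee flexion / angular velocity and pelvic attitude
# series, in the anatomical frames fixed by the calibration.

# signed twist (deg) of quaternion rows about a unit axis
twist_about_axis <- function(q, axis) {
  q <- rbind(q)
  s <- ifelse(q[, 1] < 0, -1, 1)
  q <- q * s
  rad2deg(2 * atan2(q[, 2:4, drop = FALSE] %*% axis, q[, 1]))
}

#' Knee flexion angle and angular velocity series
#'
#' Flexion is the swing-twist angle of the thigh-relative shank rotation about
#' the calibrated flexion axis (robust to ab/adduction cross-talk), zero at
#' the standing reference. The relative angular velocity is the gyro
#' difference resolved in the thigh frame via the orientation tracks.
#'
#' @param thigh_track,shank_track [estimate_orientation()] outputs on a common
#'   time base.
#' @param frames a [segment_frames()].
#' @param thigh_gyro,shank_gyro optional n x 3 gyro matrices (rad/s) matching
#'   the tracks; without them the angular velocity is derived from the tracks.
#' @return object of class `knee_series`: t, flexion (deg),
#'   angular_velocity (n x 3, thigh frame, rad/s) and its magnitude `omega`.
#' @export
knee_flexion_series <- function(thigh_track, shank_track, frames,
                                thigh_gyro = NULL, shank_gyro = NULL) {
  if (length(thigh_track$t) != length(shank_track$t) ||
      max(abs(thigh_track$t - shank_track$t)) > 1e-6)
    kg_stop("thigh and shank tracks are not on a common time base",
            "kneegait_kin_error")
  t <- thigh_track$t
  q_rel <- q_mult(q_conj(thigh_track$q), shank_track$q)
  dev <- q_mult(q_conj(frames$q_rel_std), q_rel)
  flexion <- as.numeric(twist_about_axis(dev, frames$axis_shank))
  dt <- median(diff(t))
  if (is.null(thigh_gyro)) thigh_gyro <- q_body_rates(thigh_track$q, dt)
  if (is.null(shank_gyro)) shank_gyro <- q_body_rates(shank_track$q, dt)
  w_sh_world <- q_rotate(shank_track$q, shank_gyro)
  w_th_world <- q_rotate(thigh_track$q, thigh_gyro)
  w_rel <- q_rotate(q_conj(thigh_track$q), w_sh_world - w_th_world)
  structure(list(t = t, flexion = flexion, angular_velocity = w_rel,
                 omega = sqrt(rowSums(w_rel^2))),
            class = "knee_series")
}

#' Pelvic tilt, obliquity and heading series
#'
#' Tilt (sagittal lean) and obliquity (sidewise bend) are the components of
#' the pelvis rotation relative to the standing reference about the
#' mediolateral and anteroposterior world axes; the heading (yaw, unwrapped)
#' and the pelvic gyro magnitude are carried along.
#'
#' @param pelvis_track an [estimate_orientation()] output.
#' @param frames a [segment_frames()] with a pelvis standing reference.
#' @param pelvis_gyro optional n x 3 gyro matrix (rad/s).
#' @return object of class `pelvis_series`: t, tilt, obliquity, yaw (deg),
#'   gyro_mag (rad/s).
#' @export
pelvis_series <- function(pelvis_track, frames, pelvis_gyro = NULL) {
  if (is.null(frames$q_std$pelvis))
    kg_stop("calibration has no pelvis standing capture", "kneegait_kin_error")
  t <- pelvis_track$t
  dev <- q_mult(pelvis_track$q, q_conj(rbind(frames$q_std$pelvis)))
  rv <- rad2deg(q_to_rotvec(dev))
  tilt <- as.numeric(rv %*% frames$ml_world)
  obliquity <- as.numeric(rv %*% frames$ap_world)
  yaw_raw <- atan2(2 * (pelvis_track$q[, 1] * pelvis_track$q[, 4] +
                          pelvis_track$q[, 2] * pelvis_track$q[, 3]),
                   1 - 2 * (pelvis_track$q[, 3]^2 + pelvis_track$q[, 4]^2))
  yaw <- rad2deg(unwrap_angle(yaw_raw))
  dt <- median(diff(t))
  if (is.null(pelvis_gyro)) pelvis_gyro <- q_body_rates(pelvis_track$q, dt)
  structure(list(t = t, tilt = tilt, obliquity = obliquity, yaw = yaw,
                 gyro = pelvis_gyro, gyro_mag = sqrt(rowSums(pelvis_gyro^2))),
            class = "pelvis_series")
}

unwrap_angle <- function(x) {
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(x[1], x[1] + cumsum(d))
}
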