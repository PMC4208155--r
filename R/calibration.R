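# Sensor-to-segment anatomical calibration.
#
# The knee flexion axis is identified functionally: across the three supine
# flexion poses the thigh-relative shank orientation changes by rotations
# about the (segment-fixed) hinge axis, so the axis is the dominant direction
# of the pairwise relative rotation vectors. The 5-s upright standing capture
# defines the zero-flexion reference, the pelvis neutral attitude, and -- with
# the flexion axis -- the mediolateral / anteroposterior plane directions.

QUASI_STATIC_RMS <- 0.05  # rad/s

fragment_mean_orientation <- function(stream, fusion = fusion_params()) {
  trk <- estimate_orientation(stream, fusion)
  # drop the settling half of the fragment
  keep <- trk$t >= trk$t[1] + (trk$t[length(trk$t)] - trk$t[1]) / 2
  q_mean(trk$q[keep, , drop = FALSE])
}

gyro_rms <- function(stream) sqrt(mean(stream$gyro^2) * 3)

#' Estimate anatomical segment frames from a calibration capture set
#'
#' @param calibration a [calibration_set()].
#' @param fusion [fusion_params()] used for the fragment orientations.
#' @param max_condition degeneracy guard: least pairwise pose rotation (deg)
#'   required for a usable axis fit.
#' @return object of class `segment_frames`: flexion axis in the shank and
#'   thigh sensor frames, standing reference orientations, the standing
#'   thigh-relative shank orientation (zero flexion), mediolateral /
#'   anteroposterior world directions and their sensor-frame images, and the
#'   re-estimated nominal pose angles.
#' @export
estimate_segment_frames <- function(calibration, fusion = fusion_params(),
                                    max_condition = 15) {
  cal <- calibration
  for (s in cal$standing)
    if (gyro_rms(s) > QUASI_STATIC_RMS)
      kg_stop("standing capture is not quasi-static", "kneegait_calib_error")
  for (p in cal$poses)
    for (s in p$streams)
      if (gyro_rms(s) > QUASI_STATIC_RMS)
        kg_stop("flexion pose is not quasi-static", "kneegait_calib_error")

  ord <- order(vapply(cal$poses, function(p) p$nominal_angle, 0))
  poses <- cal$poses[ord]
  q_rel <- lapply(poses, function(p) {
    qt <- fragment_mean_orientation(p$streams$thigh, fusion)
    qs <- fragment_mean_orientation(p$streams$shank, fusion)
    q_mult(q_conj(qt), qs)
  })
  pairs <- utils::combn(3, 2)
  rv <- t(apply(pairs, 2, function(ij) {
    d <- q_mult(q_conj(q_rel[[ij[1]]]), q_rel[[ij[2]]])
    as.numeric(q_to_rotvec(d))
  }))
  ang <- sqrt(rowSums(rv^2))
  if (max(ang) < deg2rad(max_condition))
    kg_stop("degenerate calibration", "kneegait_calib_error")
  # align signs with the widest pair, then take the dominant direction
  ref <- rv[which.max(ang), ] / max(ang)
  sgn <- sign(rv %*% ref)
  sgn[sgn == 0] <- 1
  sv <- svd(rv * as.numeric(sgn))
  axis_shank <- sv$v[, 1]
  # sign convention: rotating from the most extended to the most flexed pose
  # is positive flexion
  d13 <- q_to_rotvec(q_mult(q_conj(q_rel[[1]]), q_rel[[3]]))
  if (sum(d13 * axis_shank) < 0) axis_shank <- -axis_shank

  q_std <- lapply(cal$standing, fragment_mean_orientation, fusion = fusion)
  q_rel_std <- q_mult(q_conj(q_std$thigh), q_std$shank)
  axis_thigh <- as.numeric(q_rotate(q_rel_std, axis_shank))

  ml_world <- as.numeric(q_rotate(q_std$shank, axis_shank))
  ml_world[3] <- 0                                   # horizontal mediolateral
  ml_world <- ml_world / sqrt(sum(ml_world^2))
  ap_world <- as.numeric(cross3(ml_world, c(0, 0, 1)))
  ap_shank <- as.numeric(q_rotate(q_conj(q_std$shank), ap_world))

  pose_angles <- vapply(q_rel, function(qr) {
    d <- q_mult(q_conj(q_rel_std), qr)
    d <- d * sign(d[1, 1])
    rad2deg(2 * atan2(sum(d[1, 2:4] * axis_shank), d[1, 1]))
  }, 0)

  structure(list(axis_shank = axis_shank, axis_thigh = axis_thigh,
                 q_std = q_std, q_rel_std = q_rel_std,
                 ml_world = ml_world, ap_world = ap_world,
                 ap_shank = ap_shank,
                 pose_angles = pose_angles,
                 nominal_angles = vapply(poses, function(p) p$nominal_angle, 0)),
            class = "segment_frames")
}

#' @export
print.segment_frames <- function(x, ...) {
  cat(sprintf("<segment_frames> flexion axis (shank frame): [%.3f %.3f %.3f]\n",
              x$axis_shank[1], x$axis_shank[2], x$axis_shank[3]))
  cat(sprintf("  pose angles: %s (nominal %s)\n",
              paste(sprintf("%.1f", x$pose_angles), collapse = ", "),
              paste(x$nominal_angles, collapse = ", ")))
  invisible(x)
}
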