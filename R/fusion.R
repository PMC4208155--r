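# Orientation estimation: complementary quaternion filter.
#
# Gyro integration carries the orientation; the accelerometer re-anchors tilt
# (gated out during high dynamics) and the magnetometer re-anchors heading.
# The correction is gradient-descent style: at every update the estimate is
# rotated toward the accelerometer/magnetometer attitude along the error
# direction at a fixed angular-rate budget equal to the scalar gain (rad/s),
# never past the error itself. The bounded budget is what keeps residual
# linear accelerations during swing from corrupting the attitude, while it is
# ample for absorbing gyro bias; gain -> 0 degenerates to pure gyro
# integration.

#' Fusion parameters
#'
#' @param gain angular-rate budget of the corrector, rad/s (default 0.033;
#'   must exceed the expected gyro bias magnitude).
#' @param init_window quasi-static initial-pose averaging window, seconds.
#' @param acc_gate accelerometer corrections are suspended when the specific
#'   force magnitude deviates from g by more than this fraction of g.
#' @param mag_weight weight of the magnetometer error relative to the
#'   accelerometer error.
#' @param bias_gain integral gain (1/s) of the gyro-bias estimator, by
#'   default tied to the scalar gain (3 x gain); set 0 to disable.
#' @return list of class `fusion_params`.
#' @export
fusion_params <- function(gain = 0.033, init_window = 0.5, acc_gate = 0.5,
                          mag_weight = 0.5, bias_gain = 3 * gain) {
  structure(list(gain = gain, init_window = init_window, acc_gate = acc_gate,
                 mag_weight = mag_weight, bias_gain = bias_gain),
            class = "fusion_params")
}

#' Estimate a sensor's orientation track from its 9-DoF stream
#'
#' The initial pose is taken from the first `init_window` seconds assumed
#' quasi-static (accelerometer fixes tilt, magnetometer fixes heading); from
#' there the gyro is integrated and corrected toward the accelerometer /
#' magnetometer attitude by the complementary gain.
#'
#' @param stream a [sensor_stream()].
#' @param params a [fusion_params()].
#' @return object of class `orientation_track`: list with `t` and unit
#'   quaternion matrix `q` (n x 4, sensor frame -> world frame, continuous
#'   sign convention).
#' @export
estimate_orientation <- function(stream, params = fusion_params()) {
  t <- stream$t
  n <- length(t)
  dt <- 1 / stream$rate
  n0 <- max(2L, round(params$init_window * stream$rate))
  if (n < n0)
    kg_stop("stream shorter than the initialization window", "kneegait_fusion_error")
  acc0 <- colMeans(stream$accel[seq_len(n0), , drop = FALSE])
  mag0 <- colMeans(stream$mag[seq_len(n0), , drop = FALSE])
  q <- matrix(0, n, 4)
  q[1, ] <- q_from_acc_mag(acc0, mag0)

  gain <- params$gain
  mw <- params$mag_weight
  gate_lo <- GRAVITY * (1 - params$acc_gate)
  gate_hi <- GRAVITY * (1 + params$acc_gate)
  gyro <- stream$gyro; accel <- stream$accel; mag <- stream$mag
  mref <- MAG_WORLD

  cur <- q[1, ]
  bvec <- c(0, 0, 0)                      # gyro bias estimate, body frame
  ki <- params$bias_gain
  n_static <- 0L                          # consecutive quasi-static samples
  n_hold <- max(1L, round(0.40 * stream$rate))
  for (k in seq_len(n - 1L)) {
    # gyro propagation: q <- q (x) exp((w - b) dt)
    w <- (gyro[k, ] - bvec) * dt
    ang <- sqrt(sum(w * w))
    if (ang > 1e-12) {
      half <- ang / 2
      kk <- sin(half) / ang
      dq <- c(cos(half), w * kk)
      cur <- c(
        cur[1] * dq[1] - cur[2] * dq[2] - cur[3] * dq[3] - cur[4] * dq[4],
        cur[1] * dq[2] + cur[2] * dq[1] + cur[3] * dq[4] - cur[4] * dq[3],
        cur[1] * dq[3] - cur[2] * dq[4] + cur[3] * dq[1] + cur[4] * dq[2],
        cur[1] * dq[4] + cur[2] * dq[3] - cur[3] * dq[2] + cur[4] * dq[1])
    }
    if (gain > 0) {
      # world axes expressed in the body frame from the current estimate
      w1 <- cur[1]; x1 <- cur[2]; y1 <- cur[3]; z1 <- cur[4]
      # v = R' e_z (third row of R transpose): predicted "up" in body coords
      vzx <- 2 * (x1 * z1 - w1 * y1)
      vzy <- 2 * (y1 * z1 + w1 * x1)
      vzz <- 1 - 2 * (x1 * x1 + y1 * y1)
      apply_corr <- function(e, budget) {
        ea <- sqrt(sum(e * e))
        if (ea <= 1e-12) return()
        th <- min(budget * dt, ea) / 2
        kk <- sin(th) / ea
        dq <- c(cos(th), e * kk)
        cur <<- c(
          cur[1] * dq[1] - cur[2] * dq[2] - cur[3] * dq[3] - cur[4] * dq[4],
          cur[1] * dq[2] + cur[2] * dq[1] + cur[3] * dq[4] - cur[4] * dq[3],
          cur[1] * dq[3] - cur[2] * dq[4] + cur[3] * dq[1] + cur[4] * dq[2],
          cur[1] * dq[4] + cur[2] * dq[3] - cur[3] * dq[2] + cur[4] * dq[1])
      }
      gk <- gyro[k + 1L, ]
      gmag <- sqrt(sum(gk * gk))
      # during sustained standstill the gyro reads its own bias: capture it
      # with a 0.5-s low-pass (standard standstill bias capture)
      n_static <- if (gmag < 0.05) n_static + 1L else 0L
      if (n_static >= n_hold) bvec <- bvec + (dt / 0.5) * (gk - bvec)
      # tilt from the accelerometer, soft-gated on specific-force magnitude
      # and on angular rate (swing-phase accelerations are not gravity)
      a <- accel[k + 1L, ]
      an <- sqrt(sum(a * a))
      if (an > gate_lo && an < gate_hi) {
        # two confidence ramps: full trust only very near 1 g at low angular
        # rate (specific force almost pure gravity); a down-weighted loose
        # ramp keeps some authority on segments with mild dynamics
        dev <- abs(an - GRAVITY) / GRAVITY
        w_sharp <- max(0, 1 - dev / 0.1) * max(0, 1 - gmag / 3)
        w_loose <- max(0, 1 - dev / params$acc_gate) * max(0, 1 - gmag / 3)
        a <- a / an
        e_a <- c(a[2] * vzz - a[3] * vzy,
                 a[3] * vzx - a[1] * vzz,
                 a[1] * vzy - a[2] * vzx)
        apply_corr(e_a, gain * (3 * w_sharp + 0.25 * w_loose))
        w1 <- cur[1]; x1 <- cur[2]; y1 <- cur[3]; z1 <- cur[4]
        vzx <- 2 * (x1 * z1 - w1 * y1)
        vzy <- 2 * (y1 * z1 + w1 * x1)
        vzz <- 1 - 2 * (x1 * x1 + y1 * y1)
      }
      # magnetometer correction (full error vector, own budget): observes
      # every error component except rotation about the field axis, which the
      # accelerometer covers
      m <- mag[k + 1L, ]
      mn <- sqrt(sum(m * m))
      if (mn > 0) {
        m <- m / mn
        vmx <- (1 - 2 * (y1 * y1 + z1 * z1)) * mref[1] + 2 * (x1 * z1 - w1 * y1) * mref[3]
        vmy <- 2 * (x1 * y1 - w1 * z1) * mref[1] + 2 * (y1 * z1 + w1 * x1) * mref[3]
        vmz <- 2 * (x1 * z1 + w1 * y1) * mref[1] + (1 - 2 * (x1 * x1 + y1 * y1)) * mref[3]
        e_m <- c(m[2] * vmz - m[3] * vmy,
                 m[3] * vmx - m[1] * vmz,
                 m[1] * vmy - m[2] * vmx)
        apply_corr(e_m, gain * mw)
        if (ki > 0) bvec <- bvec - ki * mw * e_m * dt
      }
    }
    cur <- cur / sqrt(sum(cur * cur))
    q[k + 1L, ] <- cur
  }
  q <- q_fix_sign(q)
  structure(list(t = t, q = q, site = stream$site), class = "orientation_track")
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track> site=%s n=%d span=%.2f s\n",
              x$site %||% "?", nrow(x$q), diff(range(x$t))))
  invisible(x)
}

#' Angular error between two orientation tracks
#'
#' @param qa,qb n x 4 quaternion matrices.
#' @return per-sample rotation angle between the two attitudes, degrees.
#' @export
orientation_error_deg <- function(qa, qb) {
  rad2deg(q_angle(q_mult(q_conj(qa), qb)))
}
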