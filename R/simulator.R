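# Parametric gait simulator.
#
# A sagittal-plane kinematic leg model generates pelvis / thigh / shank
# orientation trajectories for each protocol activity, together with ground
# truth (true knee flexion, event times, true parameter values). The inverse
# of the analysis pipeline's fusion stage then synthesises 9-DoF IMU streams
# (gyro = exact body rates + bias + noise, accel = gravity + attachment-point
# linear acceleration, mag = homogeneous Earth field with 60 deg dip).
#
# Segment frames: x anterior, y left (mediolateral), z up/proximal. The knee
# is a hinge about +y; flexion is positive. Shank sagittal angular velocity is
# modelled as a slow stance lobe and an opposite fast swing lobe with zero
# crossings exactly at toe-off and heel strike, which is the pattern the event
# detector keys on. Sensors are mounted on their segments with fixed (default
# non-trivial) misalignment rotations so that the anatomical calibration is
# exercised for real.

MAG_WORLD <- c(cos(60 * pi / 180), 0, -sin(60 * pi / 180))  # 60 deg dip

#' Simulation parameters for one session
#'
#' Speed, cadence and step length are tied by speed = cadence/60 * step_length;
#' supply any two (or all three consistently, tolerance 1e-9).
#'
#' @param cadence walking cadence, steps/min.
#' @param step_length walking step length, m.
#' @param walking_speed m/s; derived if NULL.
#' @param max_knee_flexion_walk peak swing-phase knee flexion, degrees.
#' @param stance_fraction stance fraction of the gait cycle (walking).
#' @param run_speed,run_cadence,max_knee_flexion_run running equivalents
#'   (running step length is derived from the two).
#' @param stair_step_time time per staircase step, s (half an ipsilateral
#'   stride); `n_stair_steps` staircase steps per flight.
#' @param stair_contact_flexion_down,stair_contact_flexion_up knee flexion at
#'   foot contact on stairs, degrees.
#' @param stair_max_flexion_up,stair_max_flexion_down peak stair flexion, deg.
#' @param sit_to_stand_s,stand_to_sit_s TUG transfer durations, s (measured as
#'   the pelvic-tilt band-crossing interval, see vignette).
#' @param max_transfer_flexion peak knee flexion during transfers, degrees.
#' @param evasive_excursion peak pelvic sidewise bend during transfers, deg.
#' @param seated_tilt pelvic tilt while seated, degrees.
#' @param noise_sd_accel,noise_sd_gyro sensor noise SDs (m/s^2, rad/s).
#' @param gyro_bias gyro bias magnitude, rad/s (fixed random direction per
#'   sensor, drawn from the seed).
#' @param instability_gain dimensionless scale of coronal shank wobble during
#'   single-leg support (0 = stable knee).
#' @param fatigue_slope growth of pelvic evasive excursion, deg/min.
#' @param step_asymmetry ratio of alternating step durations (1 = symmetric).
#' @param rate sampling rate, Hz (50-512 accepted).
#' @param warmup_s warm-up walk duration, s.
#' @param ... further tuning knobs (see source: waveform amplitudes, sensor
#'   misalignment rotations, sprint shape).
#' @return validated list of class `gait_params`.
#' @export
gait_params <- function(cadence = 110, step_length = 0.65, walking_speed = NULL,
                        max_knee_flexion_walk = 60, stance_fraction = 0.60,
                        run_speed = 1.66, run_cadence = 160,
                        max_knee_flexion_run = 75,
                        stair_step_time = 0.5, n_stair_steps = 12,
                        stair_contact_flexion_down = 25,
                        stair_contact_flexion_up = 15,
                        stair_max_flexion_up = 80, stair_max_flexion_down = 75,
                        sit_to_stand_s = 2.2, stand_to_sit_s = 2.5,
                        max_transfer_flexion = 90, evasive_excursion = 8,
                        seated_tilt = 15,
                        noise_sd_accel = 0.15, noise_sd_gyro = 0.01,
                        gyro_bias = 0.005,
                        instability_gain = 0, fatigue_slope = 0,
                        step_asymmetry = 1.0,
                        rate = 100, warmup_s = 120, seed = 1L, ...) {
  extra <- list(...)
  if (is.null(walking_speed)) walking_speed <- cadence / 60 * step_length
  if (abs(walking_speed - cadence / 60 * step_length) > 1e-9)
    kg_stop("inconsistent parameters: speed != cadence/60 * step_length",
            "kneegait_param_error")
  if (rate < 50 || rate > 512)
    kg_stop("rate outside accepted range 50-512 Hz", "kneegait_param_error")
  p <- list(
    cadence = cadence, step_length = step_length, walking_speed = walking_speed,
    max_knee_flexion_walk = max_knee_flexion_walk,
    stance_fraction = stance_fraction,
    run_speed = run_speed, run_cadence = run_cadence,
    max_knee_flexion_run = max_knee_flexion_run,
    stair_step_time = stair_step_time, n_stair_steps = n_stair_steps,
    stair_contact_flexion_down = stair_contact_flexion_down,
    stair_contact_flexion_up = stair_contact_flexion_up,
    stair_max_flexion_up = stair_max_flexion_up,
    stair_max_flexion_down = stair_max_flexion_down,
    sit_to_stand_s = sit_to_stand_s, stand_to_sit_s = stand_to_sit_s,
    max_transfer_flexion = max_transfer_flexion,
    evasive_excursion = evasive_excursion, seated_tilt = seated_tilt,
    noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
    gyro_bias = gyro_bias,
    instability_gain = instability_gain, fatigue_slope = fatigue_slope,
    step_asymmetry = step_asymmetry,
    rate = rate, warmup_s = warmup_s, seed = as.integer(seed),
    # waveform shape
    stance_flexion = extra$stance_flexion %||% 17,
    swing_shank_excursion = extra$swing_shank_excursion %||% 50,
    tilt_amp = extra$tilt_amp %||% 3, obliquity_amp = extra$obliquity_amp %||% 2,
    bob_amp = extra$bob_amp %||% 0.025, sway_amp = extra$sway_amp %||% 0.02,
    wobble_deg = extra$wobble_deg %||% 2, wobble_hz = extra$wobble_hz %||% 6,
    # sprint
    sprint_start_cadence = extra$sprint_start_cadence %||% 100,
    sprint_peak_cadence = extra$sprint_peak_cadence %||% 170,
    sprint_n_strides = extra$sprint_n_strides %||% 7,
    stop_window = extra$stop_window %||% 0.5,
    decel_flexion = extra$decel_flexion %||% 80,
    # path lengths of the annotated walk / run trials
    walk_path_m = extra$walk_path_m %||% 100,
    run_path_m = extra$run_path_m %||% 50,
    # TUG walking
    tug_walk_m = extra$tug_walk_m %||% 3,
    # sensor mounting: rotation vectors (deg) sensor->segment, per site
    misalign = extra$misalign %||% list(pelvis = c(2, -3, 5),
                                        thigh = c(4, 3, -12),
                                        shank = c(-5, 2, 15)),
    calib_angles = extra$calib_angles %||% c(0, 45, 90)
  )
  class(p) <- "gait_params"
  p
}

#' Default parameter sets emulating a pre- or post-arthroplasty session
#'
#' Pre-surgery values follow the cohort means of the bundled example tables
#' (walking 1.19 m/s at 110 steps/min, running 1.66 m/s, sit-to-stand 2.2 s,
#' stand-to-sit 2.5 s); post-surgery values the 12-month means (1.40 m/s at
#' 120 steps/min, running 2.13 m/s, transfers 1.7 s / 1.9 s).
#'
#' @param timepoint "pre" or "post".
#' @param ... overrides passed to [gait_params()].
#' @return a `gait_params` object.
#' @export
default_params <- function(timepoint = c("pre", "post"), ...) {
  timepoint <- match.arg(timepoint)
  args <- list(...)
  base <- if (timepoint == "pre") {
    list(cadence = 110, step_length = 0.65, run_speed = 1.66,
         run_cadence = 155, max_knee_flexion_walk = 58,
         sit_to_stand_s = 2.2, stand_to_sit_s = 2.5,
         evasive_excursion = 9, instability_gain = 1,
         stair_step_time = 0.56, stair_contact_flexion_down = 14)
  } else {
    list(cadence = 120, step_length = 0.70, run_speed = 2.13,
         run_cadence = 165, max_knee_flexion_walk = 61,
         sit_to_stand_s = 1.7, stand_to_sit_s = 1.9,
         evasive_excursion = 5, instability_gain = 0.4,
         stair_step_time = 0.48, stair_contact_flexion_down = 22)
  }
  base[names(args)] <- args
  do.call(gait_params, base)
}

# raised-cosine bump: peak `peak` at `center`, support center +/- halfwidth
rc_bump <- function(t, center, halfwidth, peak = 1) {
  u <- (t - center) / halfwidth
  out <- numeric(length(t))
  i <- abs(u) < 1
  out[i] <- peak * 0.5 * (1 + cos(pi * u[i]))
  out
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# true knee flexion (deg) from segment-frame quaternion tracks: signed twist
# of the thigh-relative shank rotation about the +y hinge axis
true_flexion_from_segments <- function(q_th, q_sh) {
  qr <- q_mult(q_conj(q_th), q_sh)
  rad2deg(2 * atan2(qr[, 3], qr[, 1]))
}

# --- cyclic gait (walk / run / stairs) ----------------------------------

# Builds one cyclic activity starting at toe-off (zero shank rate, so
# segments join C1 with the inter-activity blends). Duration (n_strides+1)*T
# with heel strikes at (1-s)T + k*T, k = 0..n_strides.
gen_cyclic <- function(label, params, cadence, max_flex, pedestal = 0,
                       stance_frac = NULL, path_length = NA,
                       n_strides = NULL, rise_per_step = 0, speed = NULL) {
  dt <- 1 / params$rate
  s <- stance_frac %||% params$stance_fraction
  T <- 2 * 60 / cadence
  if (is.null(n_strides)) {
    stopifnot(is.finite(path_length), !is.null(speed))
    n_strides <- max(4, round(path_length / speed / T))
  }
  D <- (n_strides + 1) * T
  n <- round(D / dt)
  t <- (seq_len(n) - 1) * dt
  tau <- t + s * T                       # time since heel strike of cycle 0
  cyc <- floor(tau / T)
  u <- tau / T - cyc                     # cycle phase in [0,1)

  # shank sagittal angular velocity: stance lobe +, swing lobe -
  dphi <- deg2rad(params$swing_shank_excursion)
  B <- pi * dphi / (2 * s * T)
  C <- pi * dphi / (2 * (1 - s) * T)
  w_sh <- ifelse(u < s, B * sin(pi * u / s), -C * sin(pi * (u - s) / (1 - s)))
  phi_sh <- dphi / 2 + cumsum(w_sh) * dt - w_sh * dt  # starts at +dphi/2 (toe-off)

  # knee flexion waveform, degrees
  flex <- rep(pedestal, n)
  kmax <- max(cyc)
  hw_sw <- 0.35 * (1 - s) * T
  for (k in 0:kmax) {
    c_st <- (k + 0.2) * T - s * T
    c_sw <- round(((k + s + 0.45 * (1 - s)) * T - s * T) / dt) * dt  # on-grid peak
    if (pedestal == 0)
      flex <- flex + rc_bump(t, c_st, 0.15 * T, params$stance_flexion)
    flex <- flex + rc_bump(t, c_sw, hw_sw, max_flex - pedestal)
  }

  # coronal shank wobble during single-leg support, scaled by instability_gain
  psi <- rep(0, n)
  if (params$instability_gain > 0) {
    env <- numeric(n)
    for (k in 0:kmax) env <- env + rc_bump(tau, (k + 0.3) * T, 0.2 * T)
    psi <- params$instability_gain * params$wobble_deg * env *
      sin(2 * pi * params$wobble_hz * t)
  }

  # pelvis: one tilt bump per step (alternating durations d1/d2), obliquity at
  # stride frequency with fatigue growth
  r <- params$step_asymmetry
  d1 <- T * r / (1 + r); d2 <- T - d1
  # one pelvic tilt bump per step; peak spacing alternates d1/d2 so the
  # asymmetry ratio is directly what a peak-interval detector measures
  step_times <- numeric(0)
  p <- s * T + 0.3 * d1; j <- 0L
  while (p < s * T + D - 0.05) {
    step_times <- c(step_times, p)
    p <- p + if (j %% 2L == 0L) d1 else d2
    j <- j + 1L
  }
  tilt <- numeric(n)
  hw_step <- 0.35 * min(d1, d2)
  for (p in step_times) tilt <- tilt + rc_bump(tau, p, hw_step, params$tilt_amp)
  obl_amp <- params$obliquity_amp + (params$fatigue_slope / 2) * (t / 60)
  obl <- obl_amp * sin(2 * pi * tau / T)

  phi_th <- phi_sh - deg2rad(flex)
  q_sh <- q_mult(q_from_axis_angle(c(0, 1, 0), phi_sh),
                 q_from_axis_angle(c(1, 0, 0), deg2rad(psi)))
  q_th <- q_from_axis_angle(c(0, 1, 0), phi_th)
  q_pel <- q_mult(q_from_axis_angle(c(0, 1, 0), deg2rad(tilt)),
                  q_from_axis_angle(c(1, 0, 0), deg2rad(obl)))

  v_fwd <- if (is.finite(path_length)) path_length / D else
    (speed %||% (cadence / 60 * params$step_length))
  pos_pel <- cbind(v_fwd * t,
                   params$sway_amp * sin(2 * pi * tau / T),
                   0.95 + params$bob_amp * sin(4 * pi * tau / T) +
                     rise_per_step * 2 * (tau - s * T) / T)

  hs <- (1 - s) * T + (0:n_strides) * T
  to <- (1:n_strides) * T
  list(label = label, t = t, dt = dt,
       q_seg = list(pelvis = q_pel, thigh = q_th, shank = q_sh),
       pos_pel = pos_pel, yaw = rep(0, n),
       truth = list(
         flexion = true_flexion_from_segments(q_th, q_sh),
         heel_strikes = hs, toe_offs = to,
         step_times = step_times - s * T,
         params = list(speed = if (is.finite(path_length)) path_length / D else v_fwd,
                       cadence = cadence,
                       step_length = if (is.finite(path_length))
                         path_length / (2 * (n_strides + 1)) else
                           v_fwd * T / 2,
                       max_flexion = max_flex, n_strides = n_strides,
                       stride_period = T, stance_fraction = s,
                       contact_flexion = pedestal,
                       step_time = T / 2)),
       path_length = path_length)
}

gen_walk <- function(params, path_length = NA, n_strides = NULL, label = "walk") {
  gen_cyclic(label, params, params$cadence, params$max_knee_flexion_walk,
             path_length = path_length, n_strides = n_strides,
             speed = params$walking_speed)
}

gen_run <- function(params, path_length = NA, n_strides = NULL) {
  gen_cyclic("run", params, params$run_cadence, params$max_knee_flexion_run,
             stance_frac = 0.38, path_length = path_length,
             n_strides = n_strides, speed = params$run_speed)
}

gen_stairs <- function(params, direction = c("up", "down")) {
  direction <- match.arg(direction)
  T <- 2 * params$stair_step_time
  cadence <- 2 * 60 / T
  n_ipsi <- max(3, round(params$n_stair_steps / 2))
  ped <- if (direction == "up") params$stair_contact_flexion_up else
    params$stair_contact_flexion_down
  mx <- if (direction == "up") params$stair_max_flexion_up else
    params$stair_max_flexion_down
  g <- gen_cyclic(paste0("stairs_", direction), params, cadence, mx,
                  pedestal = ped, stance_frac = 0.62,
                  n_strides = n_ipsi,
                  rise_per_step = if (direction == "up") 0.17 else -0.17,
                  speed = 0.5)
  g$truth$params$step_time <- params$stair_step_time
  g
}

# --- sprint with abrupt stop --------------------------------------------

gen_sprint_stop <- function(params) {
  dt <- 1 / params$rate
  s <- 0.38
  cad <- seq(params$sprint_start_cadence, params$sprint_peak_cadence,
             length.out = params$sprint_n_strides)
  Ts <- 2 * 60 / cad
  # stride boundaries (heel strikes), with a lead-in swing of the first stride
  lead <- (1 - s) * Ts[1]
  hs <- lead + c(0, cumsum(Ts))
  stop_start <- hs[length(hs)] + s * Ts[length(Ts)] * 0.5
  D <- stop_start + params$stop_window + 0.3
  n <- round(D / dt)
  t <- (seq_len(n) - 1) * dt

  dphi <- deg2rad(params$swing_shank_excursion + 15)
  w_sh <- numeric(n); flex <- numeric(n); tilt <- numeric(n)
  add_stride <- function(t0, T, amp_scale) {
    B <- pi * dphi / (2 * s * T); C <- pi * dphi / (2 * (1 - s) * T)
    i <- t >= t0 & t < t0 + T
    u <- (t[i] - t0) / T
    w_sh[i] <<- amp_scale * ifelse(u < s, B * sin(pi * u / s),
                                   -C * sin(pi * (u - s) / (1 - s)))
    c_sw <- t0 + (s + 0.45 * (1 - s)) * T
    flex <<- flex + rc_bump(t, c_sw, 0.35 * (1 - s) * T,
                            params$max_knee_flexion_run)
    tilt <<- tilt + rc_bump(t, t0 + 0.25 * T, 0.2 * T,
                            params$tilt_amp * amp_scale) +
      rc_bump(t, t0 + 0.75 * T, 0.2 * T, params$tilt_amp * amp_scale)
  }
  # lead-in swing
  iL <- t < lead
  w_sh[iL] <- -pi * dphi / (2 * (1 - s) * Ts[1]) * sin(pi * t[iL] / lead)
  flex <- flex + rc_bump(t, lead * 0.45, 0.35 * lead, params$max_knee_flexion_run)
  for (k in seq_along(Ts)) add_stride(hs[k], Ts[k], 0.8 + 0.4 * k / length(Ts))
  # abrupt stop: shank comes to rest, deceleration flexion transient
  istop <- t >= stop_start
  w_sh[istop] <- w_sh[istop] * (1 - smoothstep((t[istop] - stop_start) /
                                                 (0.4 * params$stop_window)))
  # abrupt-stop transient: a sharp flexion catch concentrated in the first
  # quarter of the stop window
  flex <- flex + rc_bump(t, stop_start + params$stop_window / 4,
                         params$stop_window / 4, params$decel_flexion)
  phi_sh <- cumsum(w_sh) * dt
  phi_th <- phi_sh - deg2rad(flex)
  q_sh <- q_from_axis_angle(c(0, 1, 0), phi_sh)
  q_th <- q_from_axis_angle(c(0, 1, 0), phi_th)
  q_pel <- q_from_axis_angle(c(0, 1, 0), deg2rad(tilt))
  # forward speed ramps with cadence then stops
  v <- approx(c(0, hs[-1], stop_start, stop_start + params$stop_window, D),
              c(1.0, 0.8 + 2.2 * seq_along(Ts) / length(Ts), 3.0, 0, 0),
              xout = t, rule = 2)$y
  pos_pel <- cbind(cumsum(v) * dt, 0, 0.95 + params$bob_amp * sin(2 * pi * t))
  hs_in <- hs[hs < stop_start]
  to_all <- hs[seq_along(Ts)] + s * Ts
  list(label = "sprint_stop", t = t, dt = dt,
       q_seg = list(pelvis = q_pel, thigh = q_th, shank = q_sh),
       pos_pel = pos_pel, yaw = rep(0, n),
       truth = list(flexion = true_flexion_from_segments(q_th, q_sh),
                    heel_strikes = hs_in, toe_offs = to_all[to_all < stop_start],
                    step_times = numeric(0),
                    accel_window = c(0, stop_start),
                    decel_window = c(stop_start, D),
                    params = list(stop_window = params$stop_window)),
       path_length = NA)
}

# --- timed up and go -----------------------------------------------------

# sit-to-stand profile: the pelvic tilt ramps (raised cosine) from the seated
# baseline s0 to upright 0. The configured duration d is the ground-truth
# transition interval, defined as the crossing interval of the 2 deg bands;
# the full ramp is correspondingly longer (see vignette).
gen_tug <- function(params, repetition = 1L) {
  dt <- 1 / params$rate
  s0 <- params$seated_tilt
  band <- 2
  u1 <- acos(1 - 2 * band / s0) / pi          # band-leaving phase of the ramp
  span <- 1 - 2 * u1
  D1 <- params$sit_to_stand_s / span
  D2 <- params$stand_to_sit_s / span
  # seated thigh angle scaled so that knee flexion evaluated at the edge of the
  # ground-truth transition interval peaks at max_transfer_flexion
  thigh_seated <- params$max_transfer_flexion / (1 - band / s0)
  walk <- gen_walk(params, n_strides = max(2, round(params$tug_walk_m /
                                                      (2 * params$step_length))),
                   label = "walk")
  Dw <- walk$t[length(walk$t)] + dt

  seg_lens <- c(sit0 = 1.5, sts = D1, stand1 = 0.5, walk_out = Dw,
                turn1 = 1.5, walk_back = Dw, turn2 = 1.5, stand2 = 0.4,
                tts = D2, sit1 = 1.0)
  starts <- cumsum(c(0, seg_lens))[seq_along(seg_lens)]
  names(starts) <- names(seg_lens)
  D <- sum(seg_lens)
  n <- round(D / dt)
  t <- (seq_len(n) - 1) * dt

  tilt <- numeric(n); obl <- numeric(n); flex_extra <- numeric(n)
  phi_th <- numeric(n); phi_sh <- numeric(n); yaw <- numeric(n)
  v_fwd <- numeric(n)

  in_seg <- function(nm) t >= starts[nm] & t < starts[nm] + seg_lens[nm]
  prog <- function(nm) (t[in_seg(nm)] - starts[nm]) / seg_lens[nm]

  # seated
  i <- in_seg("sit0"); tilt[i] <- s0; phi_th[i] <- -deg2rad(thigh_seated)
  # sit-to-stand ramp
  i <- in_seg("sts"); v <- prog("sts"); r <- (1 + cos(pi * v)) / 2
  tilt[i] <- s0 * r; phi_th[i] <- -deg2rad(thigh_seated) * r
  obl[i] <- params$evasive_excursion * sin(pi * v)^2
  # walk out / back: splice the cyclic walk kinematics
  splice_walk <- function(nm) {
    i <- in_seg(nm)
    idx <- pmin(length(walk$t), 1 + round((t[i] - starts[nm]) / dt))
    tilt[i] <<- tilt[i] + rad2deg(2 * atan2(walk$q_seg$pelvis[idx, 3],
                                            walk$q_seg$pelvis[idx, 1]))
    phi_th[i] <<- 2 * atan2(walk$q_seg$thigh[idx, 3], walk$q_seg$thigh[idx, 1])
    phi_sh[i] <<- 2 * atan2(walk$q_seg$shank[idx, 3], walk$q_seg$shank[idx, 1])
    v_fwd[i] <<- walk$truth$params$speed
    starts[nm] + walk$truth$heel_strikes
  }
  hs_out <- splice_walk("walk_out")
  hs_back <- splice_walk("walk_back")
  # turns
  i <- in_seg("turn1"); yaw[i] <- 180 * smoothstep(prog("turn1"))
  yaw[t >= starts["turn1"] + seg_lens["turn1"] & t < starts["turn2"]] <- 180
  i <- in_seg("turn2"); yaw[i] <- 180 + 180 * smoothstep(prog("turn2"))
  yaw[t >= starts["turn2"] + seg_lens["turn2"]] <- 360
  # stand-to-sit ramp (reverse)
  i <- in_seg("tts"); v <- prog("tts"); r <- (1 - cos(pi * v)) / 2
  tilt[i] <- s0 * r; phi_th[i] <- -deg2rad(thigh_seated) * r
  obl[i] <- params$evasive_excursion * sin(pi * v)^2
  # seated at end
  i <- t >= starts["sit1"]; tilt[i] <- s0; phi_th[i] <- -deg2rad(thigh_seated)

  qz <- q_from_axis_angle(c(0, 0, 1), deg2rad(yaw))
  q_pel <- q_mult(qz, q_mult(q_from_axis_angle(c(0, 1, 0), deg2rad(tilt)),
                             q_from_axis_angle(c(1, 0, 0), deg2rad(obl))))
  q_th <- q_mult(qz, q_from_axis_angle(c(0, 1, 0), phi_th))
  q_sh <- q_mult(qz, q_from_axis_angle(c(0, 1, 0), phi_sh))
  pos_pel <- cbind(cumsum(v_fwd * cos(deg2rad(yaw))) * (1 / params$rate),
                   cumsum(v_fwd * sin(deg2rad(yaw))) * (1 / params$rate),
                   0.95 - 0.45 * tilt / s0)

  sts_int <- starts["sts"] + D1 * c(u1, 1 - u1)
  tts_int <- starts["tts"] + D2 * c(u1, 1 - u1)
  list(label = "tug", t = t, dt = 1 / params$rate,
       q_seg = list(pelvis = q_pel, thigh = q_th, shank = q_sh),
       pos_pel = pos_pel, yaw = yaw,
       truth = list(flexion = true_flexion_from_segments(q_th, q_sh),
                    heel_strikes = c(hs_out, hs_back), toe_offs = numeric(0),
                    step_times = numeric(0),
                    tug = list(repetition = repetition,
                               sit_to_stand = unname(sts_int),
                               stand_to_sit = unname(tts_int),
                               walk_out = unname(c(starts["walk_out"],
                                                   starts["turn1"])),
                               turn = unname(c(starts["turn1"],
                                               starts["turn1"] + 1.5)),
                               walk_back = unname(c(starts["walk_back"],
                                                    starts["turn2"])),
                               max_transfer_flexion = params$max_transfer_flexion,
                               evasive_excursion = params$evasive_excursion),
                    params = list()),
       path_length = NA, repetition = repetition)
}

# --- static fragments (calibration, rests) ------------------------------

gen_static <- function(params, duration, q_seg_const, label = "rest") {
  dt <- 1 / params$rate
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  rep_q <- function(q) rbind(q)[rep(1, n), , drop = FALSE]
  list(label = label, t = t, dt = dt,
       q_seg = lapply(q_seg_const, rep_q),
       pos_pel = cbind(0, 0, 0.95)[rep(1, n), , drop = FALSE],
       yaw = rep(0, n),
       truth = list(flexion = true_flexion_from_segments(
         rep_q(q_seg_const$thigh), rep_q(q_seg_const$shank)),
         heel_strikes = numeric(0), toe_offs = numeric(0),
         step_times = numeric(0), params = list()),
       path_length = NA)
}

standing_pose <- function() list(pelvis = q_identity(), thigh = q_identity(),
                                 shank = q_identity())

supine_pose <- function(knee_angle_deg) {
  base <- q_from_axis_angle(c(0, 1, 0), -pi / 2)   # lying on the back
  list(pelvis = base, thigh = base,
       shank = q_mult(base, q_from_axis_angle(c(0, 1, 0),
                                              deg2rad(knee_angle_deg))))
}

#' Generate segment kinematics for one activity
#'
#' @param activity one of walk, run, stairs_up, stairs_down, tug, sprint_stop.
#' @param params a [gait_params()] object.
#' @param path_length path length in metres for walk/run (sets the duration).
#' @return a kinematics segment: local time base, per-segment quaternion
#'   tracks (segment frames), pelvis position, and a `truth` list with the
#'   true knee flexion series, event times and parameter values.
#' @export
generate_segment_kinematics <- function(activity, params,
                                        path_length = switch(activity,
                                                             walk = 100,
                                                             run = 50, NA)) {
  activity <- match.arg(activity, c("walk", "run", "stairs_up", "stairs_down",
                                    "tug", "sprint_stop"))
  switch(activity,
         walk = gen_walk(params, path_length = path_length),
         run = gen_run(params, path_length = path_length),
         stairs_up = gen_stairs(params, "up"),
         stairs_down = gen_stairs(params, "down"),
         tug = gen_tug(params),
         sprint_stop = gen_sprint_stop(params))
}

# --- IMU synthesis ------------------------------------------------------

# sensor positions from the pelvis track and segment orientations: hip fixed
# below the pelvis sensor, thigh sensor 20 cm above the knee joint line and
# shank sensor 20 cm below it, rigid lever arms
sensor_positions <- function(kin) {
  L_th <- 0.41
  hip <- kin$pos_pel + q_rotate(kin$q_seg$pelvis, c(0.05, 0, -0.12))
  knee <- hip + q_rotate(kin$q_seg$thigh, c(0, 0, -L_th))
  list(pelvis = kin$pos_pel,
       thigh = knee + q_rotate(kin$q_seg$thigh, c(0, 0, 0.20)),
       shank = knee + q_rotate(kin$q_seg$shank, c(0, 0, -0.20)))
}

second_diff <- function(p, dt) {
  n <- nrow(p)
  if (n < 3) return(p * 0)
  a <- (p[c(2, 3:n, n), , drop = FALSE] - 2 * p +
          p[c(1, 1:(n - 2), n - 1), , drop = FALSE]) / dt^2
  a[c(1, n), ] <- 0
  a
}

#' Synthesise 9-DoF IMU streams from segment kinematics
#'
#' The gyro is the exact body-frame angular rate of the sensor orientation
#' (so that noise-free integration reproduces the orientation), plus a fixed
#' bias and white noise. The accelerometer measures specific force: gravity
#' plus the attachment-point linear acceleration, in the sensor frame. The
#' magnetometer sees a homogeneous Earth field (dip 60 deg).
#'
#' @param kin a kinematics segment from [generate_segment_kinematics()].
#' @param params a [gait_params()]; noise/bias fields are used.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param t0 session-time offset added to the local time base.
#' @return named list of three [sensor_stream()] objects plus the truth
#'   carried through (element `truth`, with sensor-frame orientation tracks).
#' @export
synthesize_imu <- function(kin, params, seed = params$seed, t0 = 0) {
  set.seed(seed)
  dt <- kin$dt
  pos <- sensor_positions(kin)
  mis <- lapply(params$misalign, function(v) q_from_rotvec(deg2rad(v)))
  streams <- list(); q_sensor <- list()
  bias_dir <- lapply(SENSOR_SITES, function(s) {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  })
  names(bias_dir) <- SENSOR_SITES
  for (site in SENSOR_SITES) {
    q <- q_fix_sign(q_mult(kin$q_seg[[site]], mis[[site]]))
    n <- nrow(q)
    gyro <- q_body_rates(q, dt) +
      matrix(params$gyro_bias * bias_dir[[site]], n, 3, byrow = TRUE)
    a_world <- second_diff(pos[[site]], dt)
    a_world[, 3] <- a_world[, 3] + GRAVITY
    accel <- q_rotate(q_conj(q), a_world)
    mag <- q_rotate(q_conj(q), MAG_WORLD)
    if (params$noise_sd_gyro > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, params$noise_sd_gyro), n, 3)
    if (params$noise_sd_accel > 0) {
      accel <- accel + matrix(stats::rnorm(3 * n, 0, params$noise_sd_accel), n, 3)
      mag <- mag + matrix(stats::rnorm(3 * n, 0, 0.01), n, 3)
    }
    streams[[site]] <- sensor_stream(site, kin$t + t0, accel, gyro, mag,
                                     rate = params$rate)
    q_sensor[[site]] <- q
  }
  truth <- kin$truth
  truth$q_sensor <- q_sensor
  truth$q_segment <- kin$q_seg
  truth$misalign <- params$misalign
  list(streams = streams, truth = truth, label = kin$label,
       path_length = kin$path_length, t0 = t0,
       duration = kin$t[length(kin$t)] + dt)
}

#' Simulate the calibration capture set
#'
#' Standing upright for 5 s plus three quasi-static supine poses at the
#' configured nominal knee flexion angles.
#' @param params a [gait_params()].
#' @param seed RNG seed.
#' @return a [calibration_set()]; attribute `truth` holds the true flexion
#'   axis in the shank and thigh sensor frames.
#' @export
simulate_calibration <- function(params, seed = params$seed) {
  st <- synthesize_imu(gen_static(params, 5, standing_pose(), "rest"),
                       params, seed = seed + 101L)
  poses <- lapply(seq_along(params$calib_angles), function(i) {
    a <- params$calib_angles[i]
    im <- synthesize_imu(gen_static(params, 2.5, supine_pose(a), "rest"),
                         params, seed = seed + 200L + i)
    list(nominal_angle = a,
         streams = im$streams[c("thigh", "shank")])
  })
  cal <- calibration_set(st$streams, poses)
  mis_sh <- q_from_rotvec(deg2rad(params$misalign$shank))
  mis_th <- q_from_rotvec(deg2rad(params$misalign$thigh))
  attr(cal, "truth") <- list(
    axis_shank = as.numeric(q_rotate(q_conj(mis_sh), c(0, 1, 0))),
    axis_thigh = as.numeric(q_rotate(q_conj(mis_th), c(0, 1, 0))))
  cal
}

# C1 blend between two poses: hold, smoothstep slerp, hold. The subject
# stands in place; only the height is interpolated.
gen_blend <- function(params, q_from, q_to, z_from, z_to,
                      hold = 0.4, move = 0.7) {
  dt <- 1 / params$rate
  D <- 2 * hold + move
  n <- round(D / dt)
  t <- (seq_len(n) - 1) * dt
  u <- smoothstep((t - hold) / move)
  q_seg <- lapply(stats::setNames(SENSOR_SITES, SENSOR_SITES), function(site) {
    d <- q_mult(q_conj(q_from[[site]]), q_to[[site]])
    rv <- q_to_rotvec(d)
    q_fix_sign(q_mult(rbind(q_from[[site]])[rep(1, n), ],
                      q_from_rotvec(rv[rep(1, n), , drop = FALSE] * u)))
  })
  pos <- cbind(0, 0, z_from + (z_to - z_from) * u)
  th <- q_seg$thigh; sh <- q_seg$shank
  list(label = "rest", t = t, dt = dt, q_seg = q_seg, pos_pel = pos,
       yaw = rep(0, n),
       truth = list(flexion = true_flexion_from_segments(th, sh),
                    heel_strikes = numeric(0), toe_offs = numeric(0),
                    step_times = numeric(0), params = list()),
       path_length = NA)
}

#' Simulate a full annotated session
#'
#' Concatenates the requested activities in protocol order (2-min warm-up
#' walk, TUG x3, 100-m walk, 50-m run, sprint with abrupt stop, four flights
#' of stairs up and down), inserting short C1 standing blends between
#' activities, and synthesises the three IMU streams plus the calibration
#' capture set.
#'
#' @param params a [gait_params()].
#' @param subject_id,timepoint,side session metadata.
#' @param activities character vector of activity slots; default full protocol.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return a [gait_session()] whose `truth` element carries ground truth
#'   (events, true flexion, per-activity true parameters, calibration axis).
#' @export
simulate_session <- function(params, subject_id = "sim", timepoint = "pre",
                             side = "right",
                             activities = c("warmup", "tug", "tug", "tug",
                                            "walk", "run", "sprint_stop",
                                            rep(c("stairs_up", "stairs_down"), 4)),
                             seed = params$seed) {
  kins <- list(); rep_tug <- 0L; rep_stairs <- c(stairs_up = 0L, stairs_down = 0L)
  for (a in activities) {
    kin <- switch(a,
                  warmup = {
                    g <- gen_walk(params,
                                  n_strides = max(4, round(params$warmup_s /
                                                             (2 * 60 / params$cadence))))
                    g$label <- "warmup"; g
                  },
                  tug = { rep_tug <- rep_tug + 1L; gen_tug(params, rep_tug) },
                  walk = gen_walk(params, path_length = params$walk_path_m),
                  run = gen_run(params, path_length = params$run_path_m),
                  sprint_stop = gen_sprint_stop(params),
                  stairs_up = { rep_stairs["stairs_up"] <- rep_stairs["stairs_up"] + 1L
                    g <- gen_stairs(params, "up"); g$repetition <- rep_stairs[["stairs_up"]]; g },
                  stairs_down = { rep_stairs["stairs_down"] <- rep_stairs["stairs_down"] + 1L
                    g <- gen_stairs(params, "down"); g$repetition <- rep_stairs[["stairs_down"]]; g },
                  kg_stop(paste0("unknown activity ", a), "kneegait_param_error"))
    kins[[length(kins) + 1]] <- kin
  }

  # stitch with blends; keep positions continuous via a running offset
  segs <- list()
  lead <- gen_static(params, 3.0, standing_pose(), "rest")
  segs[[1]] <- lead
  for (i in seq_along(kins)) {
    prev <- segs[[length(segs)]]
    np <- length(prev$t)
    q_prev <- lapply(prev$q_seg, function(q) q[np, , drop = FALSE])
    kin <- kins[[i]]
    q_next <- lapply(kin$q_seg, function(q) q[1, , drop = FALSE])
    blend <- gen_blend(params, q_prev, q_next,
                       z_from = prev$pos_pel[np, 3],
                       z_to = kin$pos_pel[1, 3])
    segs[[length(segs) + 1]] <- blend
    segs[[length(segs) + 1]] <- kin
  }
  last <- segs[[length(segs)]]
  nl <- length(last$t)
  segs[[length(segs) + 1]] <- gen_blend(
    params, lapply(last$q_seg, function(q) q[nl, , drop = FALSE]),
    lapply(standing_pose(), rbind),
    z_from = last$pos_pel[nl, 3], z_to = 0.95)
  segs[[length(segs) + 1]] <- gen_static(params, 1.0, standing_pose(), "rest")

  dt <- 1 / params$rate
  t0 <- 0; x_off <- c(0, 0, 0)
  q_all <- list(pelvis = NULL, thigh = NULL, shank = NULL)
  pos_all <- NULL; flex_all <- NULL
  ann <- list(); truth_acts <- list()
  for (sg in segs) {
    n <- length(sg$t)
    pos <- sg$pos_pel
    pos <- pos + matrix(c(x_off[1] - pos[1, 1], x_off[2] - pos[1, 2], 0),
                        n, 3, byrow = TRUE)
    for (site in SENSOR_SITES)
      q_all[[site]] <- rbind(q_all[[site]], sg$q_seg[[site]])
    pos_all <- rbind(pos_all, pos)
    flex_all <- c(flex_all, sg$truth$flexion)
    if (!sg$label %in% "rest") {
      ann[[length(ann) + 1]] <- data.frame(
        label = sg$label, t_start = t0, t_end = t0 + n * dt,
        path_length = if (is.finite(sg$path_length %||% NA)) sg$path_length else NA_real_,
        repetition = sg$repetition %||% 1L)
      tr <- sg$truth
      tr$heel_strikes <- tr$heel_strikes + t0
      tr$toe_offs <- tr$toe_offs + t0
      tr$step_times <- tr$step_times + t0
      if (!is.null(tr$tug)) {
        for (f in c("sit_to_stand", "stand_to_sit", "walk_out", "turn",
                    "walk_back"))
          tr$tug[[f]] <- tr$tug[[f]] + t0
      }
      if (!is.null(tr$accel_window)) {
        tr$accel_window <- tr$accel_window + t0
        tr$decel_window <- tr$decel_window + t0
      }
      tr$label <- sg$label
      tr$interval <- c(t0, t0 + n * dt)
      truth_acts[[length(truth_acts) + 1]] <- tr
    }
    t0 <- t0 + n * dt
    x_off <- pos[n, ]
  }
  for (site in SENSOR_SITES) q_all[[site]] <- q_fix_sign(q_all[[site]])
  full <- list(label = "session", t = (seq_len(nrow(pos_all)) - 1) * dt, dt = dt,
               q_seg = q_all, pos_pel = pos_all, yaw = NULL,
               truth = list(flexion = flex_all, heel_strikes = numeric(0),
                            toe_offs = numeric(0), step_times = numeric(0),
                            params = list()),
               path_length = NA)
  imu <- synthesize_imu(full, params, seed = seed)
  anns <- do.call(rbind, ann)
  ann_tab <- annotations(anns$label, anns$t_start, anns$t_end,
                         anns$path_length, anns$repetition)
  cal <- simulate_calibration(params, seed = seed)
  truth <- list(activities = truth_acts, flexion = flex_all,
                t = full$t, q_sensor = imu$truth$q_sensor,
                q_segment = imu$truth$q_segment,
                calibration = attr(cal, "truth"),
                params = params)
  gait_session(subject_id, timepoint, side, imu$streams, ann_tab,
               calibration = cal, truth = truth)
}

#' Simulate a matched pre/post session pair (full protocol)
#'
#' @param params_pre,params_post [gait_params()] for the two timepoints.
#' @param seed RNG seed; the pre and post sessions use derived sub-seeds.
#' @param subject_id subject identifier.
#' @param ... passed to [simulate_session()] (e.g. a reduced `activities` set).
#' @return list with elements `pre` and `post` ([gait_session()] objects).
#' @export
simulate_protocol <- function(params_pre = default_params("pre"),
                              params_post = default_params("post"),
                              seed = 1L, subject_id = "sim", ...) {
  list(pre = simulate_session(params_pre, subject_id, "pre",
                              seed = seed * 2L + 1L, ...),
       post = simulate_session(params_post, subject_id, "post",
                               seed = seed * 2L + 2L, ...))
}
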