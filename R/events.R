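# Gait event detection from the shank gyroscope, stride segmentation, stair
# steps and TUG phase transitions.
#
# Heel strikes are located at the negative-going zero crossing of the sagittal
# shank angular velocity that follows each mid-swing peak; toe-offs at the
# positive-going crossing preceding the peak. The sagittal rate is the gyro
# projected on the calibrated flexion axis, low-pass filtered, and
# sign-normalised so the mid-swing peak is positive.

sagittal_shank_rate <- function(shank_stream, frames, lowpass_hz = 6) {
  w <- as.numeric(shank_stream$gyro %*% frames$axis_shank)
  bf <- signal::butter(2, min(0.95, lowpass_hz / (shank_stream$rate / 2)))
  w <- as.numeric(signal::filtfilt(bf, w))
  if (abs(min(w)) > abs(max(w))) w <- -w
  w
}

zero_cross_time <- function(t, x, i, direction) {
  # linear-interpolated crossing between samples i and i+1
  x0 <- x[i]; x1 <- x[i + 1]
  t[i] + (t[i + 1] - t[i]) * (0 - x0) / (x1 - x0)
}

#' Detect gait events inside one annotated interval
#'
#' @param shank_stream the shank [sensor_stream()].
#' @param frames a [segment_frames()].
#' @param annotation one-row annotation (label walk, run, warmup or
#'   sprint_stop).
#' @param min_strides intervals yielding fewer strides are rejected as
#'   "too short to analyze".
#' @return object of class `gait_events`: heel_strikes, toe_offs (s), stride
#'   data.frame (start, end, duration) and single-leg-support intervals
#'   (fractions 10--50\% of each cycle after ipsilateral heel strike; an
#'   approximation documented in the vignette since no contralateral sensor
#'   exists).
#' @export
detect_gait_events <- function(shank_stream, frames, annotation,
                               min_strides = 4) {
  if (!annotation$label %in% c("walk", "run", "warmup", "sprint_stop",
                               "stairs_up", "stairs_down"))
    kg_stop("annotation label not a gait activity", "kneegait_event_error")
  sel <- shank_stream$t >= annotation$t_start & shank_stream$t <= annotation$t_end
  t <- shank_stream$t[sel]
  if (length(t) < shank_stream$rate)
    kg_stop("too short to analyze", "kneegait_event_error")
  sub <- shank_stream
  sub$t <- t; sub$gyro <- shank_stream$gyro[sel, , drop = FALSE]
  w <- sagittal_shank_rate(sub, frames)
  thr <- 0.3 * max(w)
  if (max(w) < 0.5) kg_stop("too short to analyze", "kneegait_event_error")
  pk <- pracma::findpeaks(w, minpeakheight = thr,
                          minpeakdistance = round(0.35 * shank_stream$rate))
  if (is.null(pk) || nrow(pk) < min_strides)
    kg_stop("too short to analyze", "kneegait_event_error")
  peaks <- sort(pk[, 2])
  hs <- numeric(0); to <- numeric(0)
  n <- length(w)
  for (p in peaks) {
    i <- p
    while (i < n && w[i + 1] > 0) i <- i + 1
    if (i < n && w[i] > 0 && w[i + 1] <= 0)
      hs <- c(hs, zero_cross_time(t, w, i, -1))
    j <- p
    while (j > 1 && w[j - 1] > 0) j <- j - 1
    if (j > 1 && w[j] > 0 && w[j - 1] <= 0)
      to <- c(to, zero_cross_time(t, w, j - 1, 1))
  }
  hs <- unique(hs); to <- unique(to)
  if (length(hs) < min_strides + 1)
    kg_stop("too short to analyze", "kneegait_event_error")
  strides <- data.frame(start = hs[-length(hs)], end = hs[-1])
  strides$duration <- strides$end - strides$start
  # guard against missed cycles: drop strides wildly longer than the median
  ok <- strides$duration < 1.8 * median(strides$duration)
  strides <- strides[ok, , drop = FALSE]
  sls <- cbind(strides$start + 0.10 * strides$duration,
               strides$start + 0.50 * strides$duration)
  structure(list(heel_strikes = hs, toe_offs = to, strides = strides,
                 single_leg_support = sls, annotation = annotation),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel strikes, %d toe-offs, %d strides\n",
              length(x$heel_strikes), length(x$toe_offs), nrow(x$strides)))
  invisible(x)
}

series_at <- function(t, x, when) approx(t, x, xout = when, rule = 2)$y

#' Per-stride metric table
#'
#' First and last `n_exclude` strides are flagged excluded (never dropped).
#'
#' @param events a [detect_gait_events()] result.
#' @param knee_series a [knee_flexion_series()].
#' @param shank_stream the shank [sensor_stream()].
#' @param frames a [segment_frames()].
#' @param n_exclude strides flagged at each end (default 2).
#' @return data.frame of class `stride_table`: start, end, duration,
#'   max_flexion, flexion_at_hs (deg), sagittal_peak and coronal_peak shank
#'   angular velocity within single-leg support (rad/s), excluded flag.
#' @export
segment_strides <- function(events, knee_series, shank_stream, frames,
                            n_exclude = 2) {
  st <- events$strides
  ns <- nrow(st)
  w_sag <- abs(as.numeric(shank_stream$gyro %*% frames$axis_shank))
  w_cor <- abs(as.numeric(shank_stream$gyro %*% frames$ap_shank))
  res <- st
  res$max_flexion <- NA_real_; res$flexion_at_hs <- NA_real_
  res$sagittal_peak <- NA_real_; res$coronal_peak <- NA_real_
  for (k in seq_len(ns)) {
    ik <- knee_series$t >= st$start[k] & knee_series$t <= st$end[k]
    res$max_flexion[k] <- max(knee_series$flexion[ik])
    res$flexion_at_hs[k] <- series_at(knee_series$t, knee_series$flexion,
                                      st$start[k])
    sls <- events$single_leg_support[k, ]
    is <- shank_stream$t >= sls[1] & shank_stream$t <= sls[2]
    res$sagittal_peak[k] <- max(w_sag[is])
    res$coronal_peak[k] <- max(w_cor[is])
  }
  res$excluded <- FALSE
  if (n_exclude > 0 && ns > 0) {
    idx <- unique(c(seq_len(min(n_exclude, ns)),
                    seq(max(1, ns - n_exclude + 1), ns)))
    res$excluded[idx] <- TRUE
  }
  class(res) <- c("stride_table", "data.frame")
  res
}

#' Stair step table
#'
#' Ipsilateral foot contacts are detected with the gait-event rule; since
#' staircase steps alternate feet, the time per stair step is half the
#' interval between successive ipsilateral contacts. Flexion at heel strike is
#' sampled at the contact event.
#'
#' @inheritParams segment_strides
#' @param annotation stairs_up or stairs_down annotation row.
#' @param min_steps fewer detected staircase steps reject the interval.
#' @return `stride_table` with one row per staircase step (columns as in
#'   [segment_strides()] plus `step_time`); attribute `low_confidence` is TRUE
#'   when the flexion-at-contact pattern does not look like stair gait.
#' @export
detect_stair_steps <- function(shank_stream, knee_series, frames, annotation,
                               n_exclude = 1, min_steps = 4) {
  if (!annotation$label %in% c("stairs_up", "stairs_down"))
    kg_stop("annotation is not a stair interval", "kneegait_event_error")
  ev <- detect_gait_events(shank_stream, frames, annotation, min_strides = 2)
  st <- ev$strides
  if (2 * nrow(st) < min_steps)
    kg_stop("too few stair steps", "kneegait_event_error")
  rows <- list()
  for (k in seq_len(nrow(st))) {
    ik <- knee_series$t >= st$start[k] & knee_series$t <= st$end[k]
    half <- st$duration[k] / 2
    for (h in 0:1) {
      rows[[length(rows) + 1]] <- data.frame(
        start = st$start[k] + h * half, end = st$start[k] + (h + 1) * half,
        duration = half, step_time = half,
        max_flexion = max(knee_series$flexion[ik]),
        flexion_at_hs = series_at(knee_series$t, knee_series$flexion,
                                  st$start[k]))
    }
  }
  res <- do.call(rbind, rows)
  res$excluded <- FALSE
  ns <- nrow(res)
  if (n_exclude > 0) {
    idx <- unique(c(seq_len(min(2 * n_exclude, ns)),
                    seq(max(1, ns - 2 * n_exclude + 1), ns)))
    res$excluded[idx] <- TRUE
  }
  class(res) <- c("stride_table", "data.frame")
  # level walking contacts the ground with an essentially straight knee;
  # stair gait lands visibly flexed even in the arthritic condition
  attr(res, "low_confidence") <- median(res$flexion_at_hs) < 5
  res
}

#' Segment an instrumented TUG repetition into phases
#'
#' Sit-to-stand is detected from the pelvic tilt: onset when the tilt leaves a
#' 2 deg band around the seated baseline, end when it returns within 2 deg of
#' the upright standing reference; stand-to-sit symmetrically. The turn is
#' taken from the pelvic heading, and the walk-out / walk-back phases fill the
#' gaps between transfers and turn.
#'
#' @param pelvis a [pelvis_series()].
#' @param annotation a tug annotation row.
#' @param band baseline band, degrees.
#' @return one-row data.frame of class `tug_phases`: repetition, phase
#'   intervals and durations (s).
#' @export
segment_tug <- function(pelvis, annotation, band = 2) {
  sel <- pelvis$t >= annotation$t_start & pelvis$t <= annotation$t_end
  t <- pelvis$t[sel]; tilt <- pelvis$tilt[sel]; yaw <- pelvis$yaw[sel]
  if (!length(t)) kg_stop("empty tug interval", "kneegait_event_error")
  # suppress estimation noise before threshold crossings (2 Hz low-pass)
  rate <- 1 / median(diff(t))
  tilt <- smooth_lowpass(tilt, rate, 2)
  base0 <- median(tilt[t <= t[1] + 0.5])
  base1 <- median(tilt[t >= t[length(t)] - 0.5])
  if (abs(base0) < 2 * band || abs(base1) < 2 * band)
    kg_stop("no seated tilt excursion found", "kneegait_event_error")
  up <- abs(tilt) < band
  away0 <- abs(tilt - base0) > band
  i_on <- which(away0 & t > t[1])[1]
  if (is.na(i_on)) kg_stop("no sit-to-stand excursion found", "kneegait_event_error")
  i_up <- which(up & seq_along(t) > i_on)[1]
  if (is.na(i_up)) kg_stop("no upright phase found", "kneegait_event_error")
  away1 <- abs(tilt - base1) > band
  i_off <- rev(which(away1 & t < t[length(t)]))[1]
  i_dn <- rev(which(up & seq_along(t) < i_off))[1]
  if (is.na(i_off) || is.na(i_dn))
    kg_stop("no stand-to-sit excursion found", "kneegait_event_error")
  sts <- c(t[i_on], t[i_up])
  tts <- c(t[i_dn], t[i_off])
  # half-way turn from the heading (the second turn, before sitting back
  # down, is folded into the walk-back phase end)
  dy <- abs(yaw - yaw[1])
  if (max(dy) > 90) {
    i_t0 <- which(dy > 9)[1]
    i_t1 <- which(dy > 171)[1]
    if (is.na(i_t1)) i_t1 <- which.max(dy)
    i_t2 <- which(dy > 189)[1]
    turn <- c(t[i_t0], t[i_t1])
    back_end <- if (!is.na(i_t2)) t[i_t2] else tts[1]
  } else {
    mid <- mean(c(sts[2], tts[1]))
    turn <- c(mid, mid)
    back_end <- tts[1]
  }
  out <- data.frame(repetition = annotation$repetition,
                    sit_to_stand = sts[2] - sts[1],
                    stand_to_sit = tts[2] - tts[1],
                    sts_start = sts[1], sts_end = sts[2],
                    tts_start = tts[1], tts_end = tts[2],
                    walk_out = turn[1] - sts[2],
                    turn = turn[2] - turn[1],
                    walk_back = back_end - turn[2],
                    total = tts[2] - sts[1])
  class(out) <- c("tug_phases", "data.frame")
  out
}
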