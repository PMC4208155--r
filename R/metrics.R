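# Outcome parameters per activity: spatiotemporal values over the annotated
# path length, knee flexion statistics, stair and TUG metrics, knee
# angular-velocity "power" of acceleration/deceleration, shank stability
# amplitudes, pelvic step symmetry and fatigue trends.

#' Detect steps from the pelvic tilt oscillation
#'
#' Steps appear as one pelvic tilt oscillation peak each (two per stride).
#' @param pelvis a [pelvis_series()].
#' @param annotation one annotation row.
#' @return numeric vector of step peak times, seconds.
#' @export
pelvic_step_times <- function(pelvis, annotation) {
  sel <- pelvis$t >= annotation$t_start & pelvis$t <= annotation$t_end
  t <- pelvis$t[sel]
  x <- pelvis$tilt[sel]
  x <- x - median(x)
  rate <- 1 / median(diff(t))
  bf <- signal::butter(2, min(0.95, 5 / (rate / 2)))
  x <- as.numeric(signal::filtfilt(bf, x))
  if (max(x) < 0.5) return(numeric(0))   # < 0.5 deg oscillation: no gait
  pk <- pracma::findpeaks(x, minpeakheight = 0.35 * max(x),
                          minpeakdistance = round(0.25 * rate))
  if (is.null(pk)) return(numeric(0))
  sort(t[pk[, 2]])
}

#' Spatiotemporal parameters from a path-annotated interval
#'
#' Speed is path length over interval duration; cadence and step length use
#' the pelvic step count (two steps per stride).
#'
#' @param annotation annotation row carrying `path_length`.
#' @param step_times step peak times from [pelvic_step_times()] (or a step
#'   count via `n_steps`).
#' @param n_steps optional explicit step count overriding `step_times`.
#' @return list(speed m/s, cadence steps/min, step_length m, n_steps).
#' @export
spatiotemporal <- function(annotation, step_times = NULL, n_steps = NULL) {
  if (!is.finite(annotation$path_length))
    kg_stop("annotation has no path_length", "kneegait_metric_error")
  dur <- annotation$t_end - annotation$t_start
  if (is.null(n_steps)) n_steps <- length(step_times)
  if (n_steps < 4) kg_stop("too few steps", "kneegait_metric_error")
  list(speed = annotation$path_length / dur,
       cadence = n_steps / dur * 60,
       step_length = annotation$path_length / n_steps,
       n_steps = n_steps)
}

#' Maximum-knee-flexion statistics over included strides
#' @param stride_table a [segment_strides()] table.
#' @return list(mean, range = c(min, max)) of per-stride maximum flexion, deg.
#' @export
knee_flexion_stats <- function(stride_table) {
  inc <- stride_table[!stride_table$excluded, , drop = FALSE]
  if (nrow(inc) < 4) kg_stop("fewer than 4 included strides", "kneegait_metric_error")
  list(mean = mean(inc$max_flexion),
       range = range(inc$max_flexion))
}

#' Knee angular-velocity power of acceleration and deceleration
#'
#' The sprint-with-abrupt-stop interval is split at the peak of the low-pass
#' envelope of the pelvic gyro magnitude (proxy for peak forward speed); the
#' metrics are the peak knee angular-velocity magnitude in each sub-window.
#'
#' @param knee_series a [knee_flexion_series()].
#' @param pelvis a [pelvis_series()].
#' @param annotation the sprint_stop annotation row; when absent (NULL) the
#'   metrics are absent (NULL), not zero.
#' @param agg "peak" or "q95" aggregation within the windows.
#' @return list(power_acceleration, power_deceleration) in rad/s, plus the
#'   split time.
#' @export
power_metrics <- function(knee_series, pelvis, annotation, agg = c("peak", "q95")) {
  agg <- match.arg(agg)
  if (is.null(annotation) || !nrow(annotation)) return(NULL)
  sel <- pelvis$t >= annotation$t_start & pelvis$t <= annotation$t_end
  rate <- 1 / median(diff(pelvis$t))
  env <- pelvis$gyro_mag[sel]
  bf <- signal::butter(2, min(0.95, 0.8 / (rate / 2)))
  env <- as.numeric(signal::filtfilt(bf, env))
  # deceleration onset: the envelope collapses after peak speed, so the last
  # time it is still near its maximum marks the start of the stop
  t_split <- max(pelvis$t[sel][env >= 0.9 * max(env)])
  f <- if (agg == "peak") max else function(x) quantile(x, 0.95, names = FALSE)
  ia <- knee_series$t >= annotation$t_start & knee_series$t <= t_split
  id <- knee_series$t > t_split & knee_series$t <= annotation$t_end
  list(power_acceleration = if (any(ia)) f(knee_series$omega[ia]) else NA_real_,
       power_deceleration = if (any(id)) f(knee_series$omega[id]) else NA_real_,
       t_split = t_split)
}

#' Shank stability amplitudes during single-leg support
#'
#' Median over included strides of the peak shank angular-velocity amplitude
#' in the coronal and sagittal planes within single-leg support; a surrogate
#' for mediolateral / anteroposterior knee stability.
#'
#' @param stride_table a [segment_strides()] table.
#' @return list(coronal, sagittal) in rad/s with deg/s copies
#'   (coronal_dps, sagittal_dps).
#' @export
stability_amplitude <- function(stride_table) {
  inc <- stride_table[!stride_table$excluded, , drop = FALSE]
  if (!nrow(inc)) kg_stop("no included strides", "kneegait_metric_error")
  cor <- median(inc$coronal_peak)
  sag <- median(inc$sagittal_peak)
  list(coronal = cor, sagittal = sag,
       coronal_dps = rad2deg(cor), sagittal_dps = rad2deg(sag))
}

#' Step-timing symmetry index from pelvic oscillations
#'
#' Alternating pelvic half-cycles give left and right step durations; the
#' index is min(r, 1/r) of the two mean durations, 1 = symmetric.
#'
#' @param step_times step peak times from [pelvic_step_times()].
#' @return dimensionless index in (0, 1].
#' @export
symmetry_index <- function(step_times) {
  if (length(step_times) < 9)
    kg_stop("need at least 8 steps for symmetry", "kneegait_metric_error")
  d <- diff(step_times)
  a <- mean(d[seq(1, length(d), by = 2)])
  b <- mean(d[seq(2, length(d), by = 2)])
  r <- a / b
  min(r, 1 / r)
}

#' Evasive-movement fatigue trend during walking
#'
#' Least-squares slope of per-stride pelvic evasive excursion (peak-to-peak
#' obliquity plus peak-to-peak tilt) against time, deg/min.
#'
#' @param pelvis a [pelvis_series()].
#' @param events a [detect_gait_events()] result for the interval.
#' @param annotation the walk annotation row (must span at least `min_s` s).
#' @param min_s minimum interval length, seconds.
#' @return list(slope deg/min, se, n_strides).
#' @export
fatigue_trend <- function(pelvis, events, annotation, min_s = 60) {
  if (annotation$t_end - annotation$t_start < min_s)
    kg_stop("interval too short for fatigue analysis", "kneegait_metric_error")
  st <- events$strides
  exc <- t_mid <- numeric(nrow(st))
  for (k in seq_len(nrow(st))) {
    i <- pelvis$t >= st$start[k] & pelvis$t <= st$end[k]
    exc[k] <- diff(range(pelvis$obliquity[i])) + diff(range(pelvis$tilt[i]))
    t_mid[k] <- (st$start[k] + st$end[k]) / 2
  }
  fit <- lm(exc ~ I(t_mid / 60))
  list(slope = unname(coef(fit)[2]),
       se = unname(sqrt(diag(vcov(fit)))[2]),
       n_strides = nrow(st))
}

#' TUG summary metrics over repetitions
#'
#' @param phases `tug_phases` rows from [segment_tug()] (one per repetition,
#'   rbind-ed).
#' @param knee_series a [knee_flexion_series()].
#' @param pelvis a [pelvis_series()].
#' @return list: mean sit_to_stand and stand_to_sit durations (s), mean
#'   maximum knee flexion within transfers (deg), mean peak pelvic sidewise
#'   excursion within transfers (deg).
#' @export
tug_metrics <- function(phases, knee_series, pelvis) {
  if (is.null(phases) || !nrow(phases))
    kg_stop("no valid TUG repetitions", "kneegait_metric_error")
  max_flex <- evas <- numeric(0)
  for (k in seq_len(nrow(phases))) {
    for (w in list(c(phases$sts_start[k], phases$sts_end[k]),
                   c(phases$tts_start[k], phases$tts_end[k]))) {
      i <- knee_series$t >= w[1] & knee_series$t <= w[2]
      j <- pelvis$t >= w[1] & pelvis$t <= w[2]
      max_flex <- c(max_flex, max(knee_series$flexion[i]))
      evas <- c(evas, max(abs(pelvis$obliquity[j])))
    }
  }
  list(sit_to_stand = mean(phases$sit_to_stand),
       stand_to_sit = mean(phases$stand_to_sit),
       max_transfer_flexion = mean(max_flex),
       evasive_excursion = mean(evas),
       n_repetitions = nrow(phases))
}

#' @importFrom stats vcov
NULL
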