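# Full-session analysis: raw streams -> orientation -> anatomical frames ->
# joint series -> events -> activity metrics.

#' Analyze a full session
#'
#' Runs the complete pipeline on a [gait_session()]: orientation fusion for
#' the three streams, anatomical calibration, knee and pelvis series, event
#' detection per annotated activity, and all activity metrics.
#'
#' @param session a [gait_session()] with a calibration set.
#' @param fusion [fusion_params()].
#' @param n_exclude strides excluded at each end of every interval.
#' @param strict if TRUE a failed stage aborts; otherwise the affected
#'   metrics are NA and the condition message is collected.
#' @return object of class `session_metrics`: `row` (flat one-row data.frame
#'   of all metrics), `detail` (per-activity objects: events, stride tables,
#'   TUG phases), `frames`, `knee`, `pelvis`, `issues` (character).
#' @export
analyze_session <- function(session, fusion = fusion_params(), n_exclude = 2,
                            strict = FALSE) {
  issues <- character(0)
  note <- function(e) {
    if (strict) stop(e)
    issues <<- c(issues, conditionMessage(e))
    NULL
  }
  if (is.null(session$calibration))
    kg_stop("session has no calibration set", "kneegait_calib_error")
  frames <- estimate_segment_frames(session$calibration, fusion)
  trk <- lapply(session$streams, estimate_orientation, params = fusion)
  knee <- knee_flexion_series(trk$thigh, trk$shank, frames,
                              thigh_gyro = session$streams$thigh$gyro,
                              shank_gyro = session$streams$shank$gyro)
  pelv <- pelvis_series(trk$pelvis, frames,
                        pelvis_gyro = session$streams$pelvis$gyro)
  ann <- session$annotations
  detail <- list()
  m <- list(subject_id = session$subject_id, timepoint = session$timepoint)

  walk_rows <- which(ann$label == "walk")
  if (length(walk_rows)) {
    a <- ann[walk_rows[1], ]
    res <- tryCatch({
      ev <- detect_gait_events(session$streams$shank, frames, a)
      st <- segment_strides(ev, knee, session$streams$shank, frames, n_exclude)
      steps <- pelvic_step_times(pelv, a)
      sp <- spatiotemporal(a, steps)
      fs <- knee_flexion_stats(st)
      stab <- stability_amplitude(st)
      sym <- tryCatch(symmetry_index(steps), kneegait_error = function(e) NA_real_)
      detail$walk <- list(events = ev, strides = st, steps = steps)
      list(walking_speed = sp$speed, cadence = sp$cadence,
           step_length = sp$step_length, symmetry_index = sym,
           max_knee_flexion_mean = fs$mean,
           max_knee_flexion_min = fs$range[1],
           max_knee_flexion_max = fs$range[2],
           stability_coronal = stab$coronal, stability_sagittal = stab$sagittal)
    }, kneegait_error = note)
    if (!is.null(res)) m <- c(m, res)
  }

  # fatigue needs a long walk; prefer the warm-up, fall back to the 100-m walk
  fat_rows <- which(ann$label %in% c("warmup", "walk"))
  for (i in fat_rows) {
    a <- ann[i, ]
    if (a$t_end - a$t_start < 60) next
    res <- tryCatch({
      ev <- detect_gait_events(session$streams$shank, frames, a)
      ft <- fatigue_trend(pelv, ev, a)
      list(fatigue_slope = ft$slope)
    }, kneegait_error = note)
    if (!is.null(res)) { m <- c(m, res); break }
  }

  run_rows <- which(ann$label == "run")
  if (length(run_rows)) {
    a <- ann[run_rows[1], ]
    res <- tryCatch({
      steps <- pelvic_step_times(pelv, a)
      sp <- spatiotemporal(a, steps)
      list(running_speed = sp$speed, running_cadence = sp$cadence)
    }, kneegait_error = note)
    if (!is.null(res)) m <- c(m, res)
  }

  for (dir in c("up", "down")) {
    rows <- which(ann$label == paste0("stairs_", dir))
    if (!length(rows)) next
    tabs <- list()
    for (i in rows) {
      tab <- tryCatch(detect_stair_steps(session$streams$shank, knee, frames,
                                         ann[i, ]),
                      kneegait_error = note)
      if (!is.null(tab)) tabs[[length(tabs) + 1]] <- tab
    }
    if (length(tabs)) {
      all <- do.call(rbind, lapply(tabs, as.data.frame))
      inc <- all[!all$excluded, , drop = FALSE]
      res <- stats::setNames(
        list(mean(inc$step_time), mean(inc$max_flexion)),
        paste0(c("stairs_time_per_step_", "stairs_max_flexion_"), dir))
      if (dir == "down")
        res$stairs_flexion_at_heelstrike_down <- mean(inc$flexion_at_hs)
      detail[[paste0("stairs_", dir)]] <- tabs
      m <- c(m, res)
    }
  }

  tug_rows <- which(ann$label == "tug")
  if (length(tug_rows)) {
    ph <- list()
    for (i in tug_rows) {
      p <- tryCatch(segment_tug(pelv, ann[i, ]), kneegait_error = note)
      if (!is.null(p)) ph[[length(ph) + 1]] <- p
    }
    if (length(ph)) {
      phases <- do.call(rbind, ph)
      tm <- tug_metrics(phases, knee, pelv)
      detail$tug <- phases
      m <- c(m, list(tug_sit_to_stand = tm$sit_to_stand,
                     tug_stand_to_sit = tm$stand_to_sit,
                     tug_max_transfer_flexion = tm$max_transfer_flexion,
                     tug_evasive_excursion = tm$evasive_excursion))
    }
  }

  sp_rows <- which(ann$label == "sprint_stop")
  if (length(sp_rows)) {
    res <- tryCatch({
      pm <- power_metrics(knee, pelv, ann[sp_rows[1], ])
      list(power_acceleration = pm$power_acceleration,
           power_deceleration = pm$power_deceleration)
    }, kneegait_error = note)
    if (!is.null(res)) m <- c(m, res)
  }

  row <- as.data.frame(m, stringsAsFactors = FALSE)
  structure(list(row = row, detail = detail, frames = frames, knee = knee,
                 pelvis = pelv, tracks = trk, issues = issues),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("<session_metrics>\n")
  print(t(x$row), ...)
  if (length(x$issues)) cat("issues:", paste(x$issues, collapse = "; "), "\n")
  invisible(x)
}

#' Internal consistency of spatiotemporal values
#'
#' Checks |step_length - 60 * speed / cadence| <= tol (metres) for a metrics
#' row or a pre/post cohort table.
#'
#' @param speed,cadence,step_length numeric vectors.
#' @param tol metres.
#' @return logical vector.
#' @export
check_spatiotemporal_consistency <- function(speed, cadence, step_length,
                                             tol = 0.05) {
  abs(step_length - 60 * speed / cadence) <= tol
}
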