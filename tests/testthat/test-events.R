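test_that("heel strikes match simulator truth in count and timing", {
  fx <- fix_walk()
  ses <- fx$session
  ann <- ses$annotations[ses$annotations$label == "walk", ]
  truth <- ses$truth$activities[[1]]
  ev <- fx$analysis$detail$walk$events
  expect_equal(length(ev$heel_strikes), length(truth$heel_strikes))
  matched <- vapply(truth$heel_strikes, function(h)
    min(abs(ev$heel_strikes - h)), 0)
  expect_lt(max(matched), 0.03)                  # 30 ms
  # alternating order: each toe-off falls between consecutive heel strikes
  hs <- sort(ev$heel_strikes)
  to <- sort(ev$toe_offs)
  inside <- vapply(to[to > hs[1] & to < hs[length(hs)]], function(x) {
    i <- findInterval(x, hs); x > hs[i] && x < hs[i + 1]
  }, TRUE)
  expect_true(all(inside))
  # stride durations tile the annotated interval
  st <- ev$strides
  expect_lt(abs(sum(st$duration) - (ann$t_end - ann$t_start)),
            2.5 * median(st$duration))
})

test_that("a static stream has no gait events to analyze", {
  fx <- fix_clean_cal()
  p <- fx$params
  kin <- gen_static(p, 10, standing_pose())
  imu <- synthesize_imu(kin, p, seed = 2)
  ann <- data.frame(label = "walk", t_start = 0, t_end = 9,
                    path_length = 10, repetition = 1)
  expect_error(detect_gait_events(imu$streams$shank, fx$frames, ann),
               "too short to analyze")
})

test_that("running stride count matches truth within one stride", {
  p <- gait_params(seed = 9, run_cadence = 160, run_path_m = 25)
  ses <- simulate_session(p, activities = "run", seed = 9)
  fr <- estimate_segment_frames(ses$calibration)
  ann <- ses$annotations[1, ]
  ev <- detect_gait_events(ses$streams$shank, fr, ann)
  truth <- ses$truth$activities[[1]]
  expect_lt(abs(nrow(ev$strides) - truth$params$n_strides), 1.5)
})

test_that("stride exclusion flags the requested number at each end", {
  fx <- fix_walk()
  ses <- fx$session
  fr <- fx$analysis$frames
  ev <- fx$analysis$detail$walk$events
  ks <- fx$analysis$knee
  st2 <- segment_strides(ev, ks, ses$streams$shank, fr, n_exclude = 2)
  expect_equal(sum(!st2$excluded), nrow(st2) - 4)
  expect_true(all(st2$excluded[c(1, 2, nrow(st2) - 1, nrow(st2))]))
  st0 <- segment_strides(ev, ks, ses$streams$shank, fr, n_exclude = 0)
  expect_false(any(st0$excluded))
  expect_equal(nrow(st0), nrow(ev$strides))      # flagged, never dropped
  expect_true(all(st2$duration > 0))
})

test_that("event times are stable under sensor noise within one sample", {
  p0 <- clean_params(10, walk_path_m = 15)
  kin <- generate_segment_kinematics("walk", p0, path_length = 15)
  p1 <- gait_params(seed = 10, walk_path_m = 15)   # default noise
  fr <- fix_clean_cal()$frames
  ann <- data.frame(label = "walk", t_start = 0.2,
                    t_end = max(kin$t) - 0.2, path_length = 15, repetition = 1)
  hs <- lapply(list(p0, p1), function(p) {
    imu <- synthesize_imu(kin, p, seed = 10)
    detect_gait_events(imu$streams$shank, fr, ann)$heel_strikes
  })
  expect_equal(length(hs[[1]]), length(hs[[2]]))
  expect_lt(max(abs(hs[[1]] - hs[[2]])), 0.011)  # one sample at 100 Hz
})

test_that("stair steps recover step time and contact flexion", {
  fx <- fix_mixed()
  r <- fx$analysis$row
  p <- fx$params
  expect_equal(r$stairs_time_per_step_down, p$stair_step_time,
               tolerance = 0.02)
  expect_equal(r$stairs_time_per_step_up, p$stair_step_time,
               tolerance = 0.02)
  expect_equal(r$stairs_flexion_at_heelstrike_down,
               p$stair_contact_flexion_down, tolerance = 3)
  expect_equal(r$stairs_max_flexion_down, p$stair_max_flexion_down,
               tolerance = 3)
})

test_that("a flat walk annotated as stairs is flagged low-confidence", {
  fx <- fix_walk()
  ses <- fx$session
  ann <- ses$annotations[1, ]
  ann$label <- "stairs_up"
  tab <- detect_stair_steps(ses$streams$shank, fx$analysis$knee,
                            fx$analysis$frames, ann)
  expect_true(attr(tab, "low_confidence"))
  # genuine stairs are not flagged
  mixed <- fix_mixed()
  ann2 <- mixed$session$annotations
  ann2 <- ann2[ann2$label == "stairs_down", ][1, ]
  tab2 <- detect_stair_steps(mixed$session$streams$shank,
                             mixed$analysis$knee, mixed$analysis$frames, ann2)
  expect_false(attr(tab2, "low_confidence"))
})

test_that("TUG phases are segmented per repetition with correct durations", {
  p <- default_params("pre", seed = 12)           # sit-to-stand 2.2 s
  ses <- simulate_session(p, activities = c("tug", "tug", "tug"), seed = 12)
  res <- analyze_session(ses)
  expect_equal(nrow(res$detail$tug), 3)
  expect_equal(res$row$tug_sit_to_stand, 2.2, tolerance = 0.15)
  expect_equal(res$row$tug_stand_to_sit, 2.5, tolerance = 0.15)
  expect_true(all(res$detail$tug$walk_out > 0))
  expect_true(all(res$detail$tug$turn > 0))
})

test_that("a flat signal yields no TUG transition", {
  fx <- fix_clean_cal()
  p <- fx$params
  kin <- gen_static(p, 12, standing_pose())
  imu <- synthesize_imu(kin, p, seed = 3)
  trk <- estimate_orientation(imu$streams$pelvis)
  ps <- pelvis_series(trk, fx$frames, imu$streams$pelvis$gyro)
  ann <- data.frame(label = "tug", t_start = 0, t_end = 11, repetition = 1)
  expect_error(segment_tug(ps, ann), "no seated tilt excursion")
})
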