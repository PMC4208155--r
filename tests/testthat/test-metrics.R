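test_that("spatiotemporal arithmetic follows the path-length definition", {
  ann <- data.frame(label = "walk", t_start = 0, t_end = 66.67,
                    path_length = 100, repetition = 1)
  sp <- spatiotemporal(ann, n_steps = 134)
  expect_equal(sp$speed, 100 / 66.67, tolerance = 1e-9)
  expect_equal(sp$cadence, 134 / 66.67 * 60, tolerance = 1e-9)
  expect_equal(sp$step_length, 100 / 134, tolerance = 1e-9)
  # derived values are internally consistent by construction
  expect_true(check_spatiotemporal_consistency(sp$speed, sp$cadence,
                                               sp$step_length))
  ann$path_length <- NA
  expect_error(spatiotemporal(ann, n_steps = 134), "no path_length")
})

test_that("pipeline spatiotemporal values recover the simulated gait", {
  fx <- fix_walk()
  truth <- fx$session$truth$activities[[1]]$params
  r <- fx$analysis$row
  expect_equal(r$walking_speed, truth$speed, tolerance = 0.02 * truth$speed)
  expect_lt(abs(r$cadence - truth$cadence), 1)
  expect_equal(r$step_length, truth$step_length, tolerance = 0.02)
  expect_true(check_spatiotemporal_consistency(r$walking_speed, r$cadence,
                                               r$step_length))
})

test_that("knee flexion statistics summarise included strides", {
  st <- data.frame(max_flexion = rep(60, 8), excluded = FALSE)
  fs <- knee_flexion_stats(st)
  expect_equal(fs$mean, 60)
  expect_equal(fs$range, c(60, 60))
  st2 <- data.frame(max_flexion = seq(44, 71, length.out = 10),
                    excluded = FALSE)
  expect_equal(knee_flexion_stats(st2)$range, c(44, 71))
  expect_error(knee_flexion_stats(st2[1:3, ]), "fewer than 4")
  # simulator recovery
  fx <- fix_walk()
  expect_equal(fx$analysis$row$max_knee_flexion_mean,
               fx$session$truth$activities[[1]]$params$max_flexion,
               tolerance = 3)
})

test_that("power metrics split the sprint and take the windowed peaks", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  # synthetic knee series: 2 rad/s oscillation early, 5 rad/s late
  om <- ifelse(t < 5, 2 * abs(sin(2 * pi * t)), 5 * abs(sin(2 * pi * t)))
  ks <- structure(list(t = t, flexion = t * 0, omega = om), class = "knee_series")
  # pelvis activity envelope: high until the stop at t = 5, then collapses
  env <- pmin(smoothstep(t / 1), 1 - smoothstep((t - 5) / 0.4)) * 2
  ps <- structure(list(t = t, gyro_mag = env), class = "pelvis_series")
  ann <- data.frame(label = "sprint_stop", t_start = 0, t_end = 10,
                    repetition = 1)
  pm <- power_metrics(ks, ps, ann)
  expect_equal(pm$t_split, 5, tolerance = 0.2)
  expect_equal(pm$power_acceleration, 2, tolerance = 0.05)
  expect_equal(pm$power_deceleration, 5, tolerance = 0.05)
  # constant knee angle -> zero power
  ks0 <- structure(list(t = t, flexion = t * 0, omega = t * 0),
                   class = "knee_series")
  pm0 <- power_metrics(ks0, ps, ann)
  expect_equal(pm0$power_acceleration, 0)
  # missing annotation -> absent, not zero
  expect_null(power_metrics(ks, ps, NULL))
})

test_that("sprint knee velocity peaks match the simulator truth windows", {
  p <- default_params("pre", seed = 8)
  ses <- simulate_session(p, activities = "sprint_stop", seed = 8)
  res <- analyze_session(ses)
  tr <- ses$truth$activities[[1]]
  # true peak knee angular velocity per window, from the true flexion series
  i <- ses$truth$t >= tr$interval[1] & ses$truth$t <= tr$interval[2]
  om <- abs(c(0, diff(deg2rad(ses$truth$flexion)))) * p$rate
  tacc <- max(om[i & ses$truth$t <= tr$accel_window[2]])
  tdec <- max(om[i & ses$truth$t > tr$decel_window[1]])
  # the detected split may sit within a stride of the true deceleration
  # onset, so allow the acceleration peak a full-window slack of 15 %
  expect_equal(res$row$power_acceleration, tacc, tolerance = 0.15 * tacc)
  expect_equal(res$row$power_deceleration, tdec, tolerance = 0.1 * tdec)
})

test_that("stability amplitudes scale linearly with joint instability", {
  co <- vapply(c(1, 2), function(g) {
    p <- gait_params(seed = 9, instability_gain = g, walk_path_m = 30)
    ses <- simulate_session(p, activities = "walk", seed = 9)
    analyze_session(ses)$row$stability_coronal
  }, 0)
  expect_equal(co[2] / co[1], 2, tolerance = 0.1)
  # stable knee: coronal well below sagittal
  fx <- fix_walk()                                # instability_gain 0
  r <- fx$analysis$row
  expect_lt(r$stability_coronal, 0.05 * r$stability_sagittal)
})

test_that("step symmetry reflects simulated timing asymmetry", {
  expect_equal(symmetry_index(seq(0, 8, by = 0.5)), 1.0)
  expect_error(symmetry_index(c(0, 0.5)), "at least 8 steps")
  p <- gait_params(seed = 4, step_asymmetry = 0.9, walk_path_m = 30)
  ses <- simulate_session(p, activities = "walk", seed = 4)
  expect_equal(analyze_session(ses)$row$symmetry_index, 0.90,
               tolerance = 0.02)
})

test_that("fatigue slope is recovered and the null case stays near zero", {
  p2 <- gait_params(seed = 6, fatigue_slope = 2, warmup_s = 80)
  ses2 <- simulate_session(p2, activities = "warmup", seed = 6)
  r2 <- analyze_session(ses2)$row
  expect_equal(r2$fatigue_slope, 2, tolerance = 0.5)
  p0 <- gait_params(seed = 6, fatigue_slope = 0, warmup_s = 80)
  ses0 <- simulate_session(p0, activities = "warmup", seed = 6)
  fr <- estimate_segment_frames(ses0$calibration)
  trk <- lapply(ses0$streams, estimate_orientation)
  ps <- pelvis_series(trk$pelvis, fr, ses0$streams$pelvis$gyro)
  ann <- ses0$annotations[1, ]
  ev <- detect_gait_events(ses0$streams$shank, fr, ann)
  ft <- fatigue_trend(ps, ev, ann)
  expect_lt(abs(ft$slope), 2 * ft$se + 0.2)      # CI contains zero
  ann$t_end <- ann$t_start + 30
  expect_error(fatigue_trend(ps, ev, ann), "too short")
})

test_that("TUG metrics aggregate repetitions and evasive excursion", {
  p <- default_params("post", seed = 13, evasive_excursion = 8)
  ses <- simulate_session(p, activities = c("tug", "tug", "tug"), seed = 13)
  r <- analyze_session(ses)$row
  expect_equal(r$tug_sit_to_stand, 1.7, tolerance = 0.1)
  expect_equal(r$tug_evasive_excursion, 8, tolerance = 1)
  expect_equal(r$tug_max_transfer_flexion, p$max_transfer_flexion,
               tolerance = 3)
  expect_error(tug_metrics(NULL, NULL, NULL), "no valid TUG")
})
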