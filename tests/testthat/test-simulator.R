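test_that("speed-cadence-step-length consistency is enforced at construction", {
  p <- gait_params(cadence = 120, step_length = 0.75)
  expect_equal(p$walking_speed, 1.5)
  expect_equal(100 / p$walking_speed, 66.67, tolerance = 1e-3)
  expect_error(gait_params(cadence = 120, step_length = 0.75,
                           walking_speed = 1.4),
               "inconsistent")
  expect_error(gait_params(rate = 20), "accepted range")
})

test_that("true knee flexion peaks exactly at the configured maximum", {
  p <- clean_params(1, max_knee_flexion_walk = 60)
  kin <- generate_segment_kinematics("walk", p, path_length = 20)
  expect_equal(max(kin$truth$flexion), 60, tolerance = 1e-6)
  expect_true(all(kin$truth$flexion > -5 & kin$truth$flexion < 150))
  # C1 check: finite-difference angular rate of the shank stays bounded
  w <- q_body_rates(kin$q_seg$shank, kin$dt)
  expect_lt(max(abs(diff(w[, 2]))) / kin$dt, 200)  # rad/s^2, no jumps
})

test_that("TUG ground-truth transition interval equals the configured duration", {
  p <- clean_params(1, sit_to_stand_s = 2.2, stand_to_sit_s = 2.5)
  kin <- generate_segment_kinematics("tug", p)
  expect_equal(diff(kin$truth$tug$sit_to_stand), 2.2, tolerance = 1e-9)
  expect_equal(diff(kin$truth$tug$stand_to_sit), 2.5, tolerance = 1e-9)
})

test_that("IMU synthesis honours the static and constant-rate closed forms", {
  p <- clean_params(1)
  kin <- gen_static(p, 2, standing_pose())
  imu <- synthesize_imu(kin, p, seed = 1)
  acc <- imu$streams$shank$accel
  expect_equal(unname(sqrt(rowSums(acc^2))), rep(9.81, nrow(acc)),
               tolerance = 1e-9)
  expect_equal(max(abs(imu$streams$shank$gyro)), 0, tolerance = 1e-12)

  # constant 90 deg/s about one axis -> gyro magnitude pi/2 exactly
  dt <- 1 / p$rate
  t <- seq(0, 1, by = dt)
  qrot <- q_from_axis_angle(c(0, 0, 1), pi / 2 * t)
  kin2 <- gen_static(p, 1 + dt, standing_pose())
  kin2$q_seg <- lapply(kin2$q_seg, function(q) q_mult(qrot, q))
  imu2 <- synthesize_imu(kin2, p, seed = 1)
  gm <- sqrt(rowSums(imu2$streams$pelvis$gyro^2))
  expect_equal(unname(gm[-length(gm)]), rep(pi / 2, length(gm) - 1),
               tolerance = 1e-9)
})

test_that("identical seeds give bit-identical sessions", {
  p <- gait_params(seed = 4, walk_path_m = 12)
  s1 <- simulate_session(p, activities = "walk", seed = 4)
  s2 <- simulate_session(p, activities = "walk", seed = 4)
  expect_identical(s1$streams$shank$gyro, s2$streams$shank$gyro)
  expect_identical(s1$streams$pelvis$accel, s2$streams$pelvis$accel)
  s3 <- simulate_session(p, activities = "walk", seed = 5)
  expect_false(identical(s1$streams$shank$gyro, s3$streams$shank$gyro))
})

test_that("integrating the noise-free gyro reproduces the orientation", {
  p <- clean_params(2, warmup_s = 60)
  ses <- simulate_session(p, activities = "warmup", seed = 2)
  for (site in c("thigh", "shank")) {
    st <- ses$streams[[site]]
    q <- ses$truth$q_sensor[[site]]
    dt <- 1 / st$rate
    qi <- q[1, , drop = FALSE]
    cur <- q[1, ]
    worst <- 0
    for (k in seq_len(nrow(q) - 1)) {
      cur <- q_mult(cur, q_from_rotvec(rbind(st$gyro[k, ] * dt)))
      if (k %% 500 == 0)
        worst <- max(worst, q_angle(q_mult(q_conj(cur), q[k + 1, ])))
    }
    expect_lt(rad2deg(worst), 0.5)
  }
})

test_that("ground-truth step count matches cadence times duration", {
  for (sd in c(1, 2)) {
    p <- clean_params(sd, cadence = 108 + 6 * sd, walk_path_m = 30)
    kin <- generate_segment_kinematics("walk", p, path_length = 30)
    dur <- length(kin$t) * kin$dt
    expect_lt(abs(length(kin$truth$step_times) - p$cadence / 60 * dur), 1.01)
  }
})

test_that("zero instability gain leaves the coronal channel clean", {
  p <- clean_params(3, instability_gain = 0)
  kin <- generate_segment_kinematics("walk", p, path_length = 20)
  imu <- synthesize_imu(kin, p, seed = 3)
  g <- imu$streams$shank$gyro
  mis <- q_from_rotvec(deg2rad(p$misalign$shank))
  ax_sag <- as.numeric(q_rotate(q_conj(mis), c(0, 1, 0)))
  ax_cor <- as.numeric(q_rotate(q_conj(mis), c(1, 0, 0)))
  expect_lt(max(abs(g %*% ax_cor)), 0.05 * max(abs(g %*% ax_sag)))
})

test_that("the full protocol session is annotated in protocol order", {
  p <- default_params("pre", seed = 1, warmup_s = 20, walk_path_m = 15,
                      run_path_m = 10)
  ses <- simulate_session(p, seed = 1)
  lab <- ses$annotations$label
  expect_equal(lab[1:7], c("warmup", "tug", "tug", "tug", "walk", "run",
                           "sprint_stop"))
  expect_equal(lab[8:15], rep(c("stairs_up", "stairs_down"), 4))
  expect_equal(ses$annotations$path_length[lab == "walk"], 15)
  expect_equal(ses$annotations$repetition[lab == "tug"], 1:3)
  # annotations non-overlapping by construction of the annotations class
  expect_s3_class(ses$annotations, "annotations")
})

test_that("simulate_protocol returns a matched pre/post pair", {
  pair <- simulate_protocol(default_params("pre", warmup_s = 15, walk_path_m = 12,
                                           run_path_m = 10),
                            default_params("post", warmup_s = 15, walk_path_m = 12,
                                           run_path_m = 10),
                            seed = 2, activities = c("walk"))
  expect_equal(pair$pre$timepoint, "pre")
  expect_equal(pair$post$timepoint, "post")
  expect_equal(pair$pre$subject_id, pair$post$subject_id)
})
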