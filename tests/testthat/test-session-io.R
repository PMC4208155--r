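make_stream_df <- function(n = 10, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  data.frame(t = t, ax = 0, ay = 0, az = 9.81,
             gx = 0.01, gy = -0.02, gz = 0.03,
             mx = 0.5, my = 0, mz = -0.866)
}

test_that("well-formed stream files read back with rate and length intact", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(make_stream_df(10), f, row.names = FALSE)
  s <- read_stream(f, "shank")
  expect_s3_class(s, "sensor_stream")
  expect_equal(length(s$t), 10)
  expect_equal(s$rate, 100)
  expect_equal(unname(s$gyro[1, ]), c(0.01, -0.02, 0.03))
  # magnetometer is unit-normalised on load
  expect_equal(unname(sqrt(rowSums(s$mag^2))), rep(1, 10), tolerance = 1e-9)

  # write/read round trip
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_stream(s, f2)
  s2 <- read_stream(f2, "shank")
  expect_equal(s2$accel, s$accel, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(s2$gyro, s$gyro, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gap policy interpolates single dropped samples and logs it", {
  d <- make_stream_df(1000)
  d$az <- 9.81 + sin(seq_len(1000) / 50)
  dropped <- d[-500, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(dropped, f, row.names = FALSE)
  expect_warning(s <- read_stream(f, "thigh"), "interpolated 1 missing")
  expect_equal(length(s$t), 1000)
  # interpolated value is the midpoint of its neighbours
  expect_equal(unname(s$accel[500, 3]), (d$az[499] + d$az[501]) / 2,
               tolerance = 1e-9)
})

test_that("corrupt streams are rejected, never silently loaded", {
  d <- make_stream_df(20)
  d$t <- rev(d$t)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_error(read_stream(f, "shank"), "non-monotonic time")

  # a gap longer than 10 samples
  d <- make_stream_df(2000)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[-(100:115), ], f2, row.names = FALSE)
  expect_error(read_stream(f2, "shank"), "gap longer")

  # > 1% of samples missing (scattered single-sample gaps)
  d <- make_stream_df(300)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[-seq(10, 290, by = 20), ], f3, row.names = FALSE)
  expect_error(read_stream(f3, "shank"), "missing")
})

test_that("deg/s gyro header flag converts to rad/s", {
  d <- make_stream_df(10)
  d$gx <- 90  # deg/s
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# gyro_units: deg/s",
               paste(names(d), collapse = ",")), f)
  write.table(d, f, sep = ",", row.names = FALSE, col.names = FALSE,
              append = TRUE)
  s <- read_stream(f, "shank")
  expect_equal(unname(s$gyro[1, 1]), pi / 2, tolerance = 1e-9)
})

test_that("annotation files validate labels, overlap and path lengths", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("label,t_start,t_end,path_length,repetition\nwalk,0,80,100,1", f)
  a <- read_annotations(f)
  expect_equal(nrow(a), 1)
  expect_equal(a$path_length, 100)

  writeLines("label,t_start,t_end,path_length,repetition", f)
  expect_equal(nrow(read_annotations(f)), 0)

  expect_error(annotations(c("walk", "walk"), c(0, 40), c(50, 90),
                           c(100, 100), 1:2),
               "overlapping")
  expect_error(annotations("walk", 0, 80, NA, 1), "path_length")
  expect_error(annotations("hop", 0, 10, NA, 1), "unknown annotation label")
})

test_that("clinical score tables are range-checked", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,timepoint,kss,oks,ucla,satisfaction",
               "1,pre,38,18,7,satisfied"), f)
  sc <- read_clinical_scores(f)
  expect_equal(sc$kss, 38)
  writeLines(c("subject_id,timepoint,kss,oks,ucla,satisfaction",
               "1,pre,120,18,7,satisfied"), f)
  expect_error(read_clinical_scores(f), "KSS out of range")
  writeLines(c("subject_id,timepoint,kss,oks,ucla,satisfaction",
               "1,pre,90,49,7,satisfied"), f)
  expect_error(read_clinical_scores(f), "OKS out of range")
})

test_that("reports are rounded half-away-from-zero and byte-deterministic", {
  expect_equal(round_half_away(1.4444, 2), 1.44)
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
  expect_equal(round_half_away(76.5, 0), 77)

  rep <- data.frame(subject_id = "p1", walking_speed = 1.4444,
                    max_knee_flexion_mean = 57.84, tug_sit_to_stand = 2.1999)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, f1)
  write_report(rep, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  txt <- readLines(f1)
  expect_match(txt[2], "1.44")      # speeds: 2 dp
  expect_match(txt[2], ",58,")      # angles: whole degrees
  expect_match(txt[2], "2.20")      # times: 2 dp
  back <- read_report(f1)
  expect_equal(back$walking_speed, 1.44)
  expect_equal(back$max_knee_flexion_mean, 58)
})

test_that("a simulated session survives a write/read round trip", {
  p <- clean_params(2, walk_path_m = 15)
  ses <- simulate_session(p, activities = "walk", seed = 2)
  dir <- withr::local_tempdir()
  man <- write_session(ses, dir)
  back <- read_session(man)
  expect_equal(back$subject_id, ses$subject_id)
  expect_equal(back$side, ses$side)
  expect_equal(as.data.frame(back$annotations),
               as.data.frame(ses$annotations), tolerance = 1e-9)
  for (site in c("pelvis", "thigh", "shank")) {
    expect_equal(back$streams[[site]]$gyro, ses$streams[[site]]$gyro,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$streams[[site]]$accel, ses$streams[[site]]$accel,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(length(back$calibration$poses), 3)
  expect_equal(back$calibration$poses[[2]]$nominal_angle,
               ses$calibration$poses[[2]]$nominal_angle)
})
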