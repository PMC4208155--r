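# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noise-free parameter set (no sensor noise, no bias)
clean_params <- function(seed = 1L, ...) {
  gait_params(noise_sd_accel = 0, noise_sd_gyro = 0, gyro_bias = 0,
              seed = seed, ...)
}

# noise-free calibration and its frames
fix_clean_cal <- function() memo("clean_cal", {
  p <- clean_params(1)
  cal <- simulate_calibration(p, seed = 1)
  list(params = p, cal = cal, frames = estimate_segment_frames(cal),
       truth = attr(cal, "truth"))
})

# default-noise 40-m walk session + full analysis
fix_walk <- function() memo("walk", {
  p <- gait_params(seed = 7, walk_path_m = 40)
  ses <- simulate_session(p, activities = "walk", seed = 7)
  list(params = p, session = ses, analysis = analyze_session(ses))
})

# short session with stairs and one TUG repetition
fix_mixed <- function() memo("mixed", {
  p <- default_params("pre", seed = 5, walk_path_m = 40)
  ses <- simulate_session(p, activities = c("stairs_up", "stairs_down", "tug"),
                          seed = 5)
  list(params = p, session = ses, analysis = analyze_session(ses))
})

# angle between two unit 3-vectors, degrees, sign-insensitive
axis_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

random_unit_quat <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}
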