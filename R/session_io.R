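# Reading and writing sensor streams, annotations, calibration captures,
# clinical score tables and analysis reports.
#
# On-disk formats are plain text. A stream file is a CSV with header
# t,ax,ay,az,gx,gy,gz,mx,my,mz (SI units: s, m/s^2, rad/s, arbitrary mag
# units); an optional leading comment line "# gyro_units: deg/s" declares
# degree-per-second gyro logs, which are converted on load.

SENSOR_SITES <- c("pelvis", "thigh", "shank")
ANNOTATION_LABELS <- c("warmup", "tug", "walk", "run", "sprint_stop",
                       "stairs_up", "stairs_down", "transfer", "rest")

#' Construct a validated sensor stream
#'
#' @param site one of "pelvis", "thigh", "shank".
#' @param t numeric vector of timestamps, seconds, strictly increasing.
#' @param accel,gyro,mag n x 3 matrices (m/s^2, rad/s, arbitrary units).
#'   Magnetometer rows are unit-normalised.
#' @param rate sampling rate in Hz; estimated from `t` when missing.
#' @return object of class `sensor_stream`.
#' @export
sensor_stream <- function(site, t, accel, gyro, mag, rate = NULL) {
  site <- match.arg(site, SENSOR_SITES)
  t <- as.numeric(t)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  n <- length(t)
  if (n < 2) kg_stop("stream too short", "kneegait_io_error")
  if (any(diff(t) <= 0)) kg_stop("non-monotonic time", "kneegait_io_error")
  if (nrow(accel) != n || nrow(gyro) != n || nrow(mag) != n ||
      ncol(accel) != 3 || ncol(gyro) != 3 || ncol(mag) != 3)
    kg_stop("channel lengths differ from time base", "kneegait_io_error")
  if (anyNA(accel) || anyNA(gyro) || anyNA(mag) || anyNA(t))
    kg_stop("missing samples after load", "kneegait_io_error")
  if (is.null(rate)) rate <- 1 / median(diff(t))
  if (rate <= 0) kg_stop("rate must be positive", "kneegait_io_error")
  mn <- sqrt(rowSums(mag^2))
  mag <- mag / ifelse(mn > 0, mn, 1)
  structure(list(site = site, t = t, accel = accel, gyro = gyro, mag = mag,
                 rate = rate),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> site=%s n=%d rate=%.1f Hz span=%.2f s\n",
              x$site, length(x$t), x$rate, diff(range(x$t))))
  invisible(x)
}

#' Read a 9-DoF sensor stream from CSV
#'
#' Applies the gap policy: runs of up to 10 consecutive missing samples are
#' filled by linear interpolation (with a warning stating the count); longer
#' runs, more than 1\% missing overall, or non-monotonic timestamps are
#' rejected.
#'
#' @param path CSV file with columns t,ax,ay,az,gx,gy,gz,mx,my,mz.
#' @param site sensor site the file belongs to.
#' @return a [sensor_stream()].
#' @export
read_stream <- function(path, site) {
  if (!file.exists(path)) kg_stop(paste0("no such file: ", path), "kneegait_io_error")
  first <- readLines(path, n = 1L)
  deg_gyro <- grepl("gyro_units\\s*:\\s*deg/s", first)
  d <- read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  if (!all(need %in% names(d)))
    kg_stop("stream header must declare t,ax,ay,az,gx,gy,gz,mx,my,mz",
            "kneegait_io_error")
  t <- d$t
  if (any(diff(t) <= 0)) kg_stop("non-monotonic time", "kneegait_io_error")
  dt <- median(diff(t))
  n_exp <- round((t[length(t)] - t[1]) / dt) + 1L
  vals <- as.matrix(d[need[-1]])
  if (n_exp > length(t)) {
    steps <- round(diff(t) / dt)
    if (max(steps) - 1 > 10)
      kg_stop("gap longer than 10 samples", "kneegait_io_error")
    missing <- n_exp - length(t)
    if (missing / n_exp > 0.01)
      kg_stop("more than 1% missing samples", "kneegait_io_error")
    grid <- t[1] + dt * (seq_len(n_exp) - 1L)
    vals <- apply(vals, 2, function(col) approx(t, col, xout = grid)$y)
    t <- grid
    warning(sprintf("interpolated %d missing sample(s) in %s", missing, path))
  }
  gyro <- vals[, c("gx", "gy", "gz")]
  if (deg_gyro) gyro <- gyro * DEG
  sensor_stream(site, t,
                accel = vals[, c("ax", "ay", "az")],
                gyro = gyro,
                mag = vals[, c("mx", "my", "mz")],
                rate = 1 / dt)
}

#' Write a sensor stream to CSV (SI units)
#' @param stream a [sensor_stream()].
#' @param path output file.
#' @export
write_stream <- function(stream, path) {
  d <- data.frame(t = stream$t,
                  ax = stream$accel[, 1], ay = stream$accel[, 2], az = stream$accel[, 3],
                  gx = stream$gyro[, 1], gy = stream$gyro[, 2], gz = stream$gyro[, 3],
                  mx = stream$mag[, 1], my = stream$mag[, 2], mz = stream$mag[, 3])
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated annotation table
#' @param label,t_start,t_end,path_length,repetition vectors of equal length.
#' @return data.frame of class `annotations`, sorted by t_start.
#' @export
annotations <- function(label, t_start, t_end, path_length = NA_real_,
                        repetition = 1L) {
  d <- data.frame(label = as.character(label), t_start = t_start,
                  t_end = t_end, path_length = as.numeric(path_length),
                  repetition = as.integer(repetition))
  bad <- setdiff(unique(d$label), ANNOTATION_LABELS)
  if (length(bad))
    kg_stop(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")),
            "kneegait_io_error")
  if (any(d$t_start >= d$t_end))
    kg_stop("annotation with t_start >= t_end", "kneegait_io_error")
  d <- d[order(d$t_start), , drop = FALSE]
  if (nrow(d) > 1 && any(d$t_start[-1] < d$t_end[-nrow(d)] - 1e-9))
    kg_stop("overlapping annotation intervals", "kneegait_io_error")
  need_path <- d$label %in% c("walk", "run")
  if (any(need_path & !is.finite(d$path_length)))
    kg_stop("walk/run annotation without path_length", "kneegait_io_error")
  rownames(d) <- NULL
  class(d) <- c("annotations", "data.frame")
  d
}

#' Read an annotation track from CSV
#' @param path CSV with columns label,t_start,t_end,path_length,repetition.
#' @return validated, sorted `annotations` data.frame (empty file gives an
#'   empty table).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) kg_stop(paste0("no such file: ", path), "kneegait_io_error")
  d <- tryCatch(read.csv(path), error = function(e) NULL)
  if (is.null(d) || nrow(d) == 0) {
    d <- data.frame(label = character(), t_start = numeric(), t_end = numeric(),
                    path_length = numeric(), repetition = integer())
    class(d) <- c("annotations", "data.frame")
    return(d)
  }
  annotations(d$label, d$t_start, d$t_end,
              d$path_length %||% NA_real_, d$repetition %||% 1L)
}

#' @rdname read_annotations
#' @param ann annotations table.
#' @export
write_annotations <- function(ann, path) {
  write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-patient clinical score table
#'
#' @param path CSV with columns subject_id,timepoint,kss,oks,ucla,satisfaction.
#'   KSS 0-100, OKS 0-48, UCLA 1-10; timepoint "pre" or "post".
#' @return validated data.frame.
#' @export
read_clinical_scores <- function(path) {
  d <- read.csv(path)
  need <- c("subject_id", "timepoint", "kss", "oks")
  if (!all(need %in% names(d)))
    kg_stop("scores file must have subject_id,timepoint,kss,oks", "kneegait_io_error")
  if (!all(d$timepoint %in% c("pre", "post")))
    kg_stop("timepoint must be pre or post", "kneegait_io_error")
  if (any(d$kss < 0 | d$kss > 100, na.rm = TRUE))
    kg_stop("KSS out of range 0-100", "kneegait_io_error")
  if (any(d$oks < 0 | d$oks > 48, na.rm = TRUE))
    kg_stop("OKS out of range 0-48", "kneegait_io_error")
  if (!is.null(d$ucla) && any(d$ucla < 1 | d$ucla > 10, na.rm = TRUE))
    kg_stop("UCLA out of range 1-10", "kneegait_io_error")
  d
}

#' Assemble a three-sensor recording session
#'
#' @param subject_id identifier.
#' @param timepoint "pre" or "post".
#' @param side instrumented side, "left" or "right".
#' @param streams named list with elements pelvis, thigh, shank
#'   (each a [sensor_stream()]), time-aligned to a common clock.
#' @param annotations an `annotations` table.
#' @param calibration a calibration set (see [calibration_set()]), or NULL.
#' @param truth optional simulator ground truth (kept for testing).
#' @return object of class `gait_session`.
#' @export
gait_session <- function(subject_id, timepoint, side, streams, annotations,
                         calibration = NULL, truth = NULL) {
  timepoint <- match.arg(timepoint, c("pre", "post"))
  side <- match.arg(side, c("left", "right"))
  if (!all(SENSOR_SITES %in% names(streams)))
    kg_stop("all three sensor sites (pelvis, thigh, shank) are required",
            "kneegait_io_error")
  t0 <- vapply(streams[SENSOR_SITES], function(s) s$t[1], 0)
  dt <- 1 / streams$pelvis$rate
  if (diff(range(t0)) > dt)
    kg_stop("streams not time-aligned (offset exceeds one sample)",
            "kneegait_io_error")
  structure(list(subject_id = subject_id, timepoint = timepoint, side = side,
                 streams = streams[SENSOR_SITES], annotations = annotations,
                 calibration = calibration, truth = truth),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> subject=%s timepoint=%s side=%s  %d annotation(s), %.0f s\n",
              x$subject_id, x$timepoint, x$side, nrow(x$annotations),
              diff(range(x$streams$pelvis$t))))
  invisible(x)
}

#' Quasi-static calibration capture set
#'
#' @param standing named list of the three standing streams (>= 5 s upright).
#' @param poses list of supine flexion poses, each a list with elements
#'   `nominal_angle` (deg) and `streams` (thigh + shank sensor streams).
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(standing, poses) {
  if (!all(c("thigh", "shank") %in% names(standing)))
    kg_stop("standing capture needs at least thigh and shank streams",
            "kneegait_io_error")
  if (length(poses) != 3)
    kg_stop("exactly three flexion poses required", "kneegait_io_error")
  ang <- vapply(poses, function(p) p$nominal_angle, 0)
  if (length(unique(ang)) != 3)
    kg_stop("flexion pose nominal angles must be distinct", "kneegait_io_error")
  structure(list(standing = standing, poses = poses), class = "calibration_set")
}

#' Write a session (streams, annotations, manifest) to a directory
#'
#' @param session a [gait_session()].
#' @param dir output directory (created if needed).
#' @param name file-name stem; defaults to `<subject>_<timepoint>`.
#' @return path of the YAML manifest, invisibly.
#' @export
write_session <- function(session, dir, name = NULL) {
  name <- name %||% paste0(session$subject_id, "_", session$timepoint)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(subject_id = session$subject_id, timepoint = session$timepoint,
              side = session$side, streams = list(), annotations = NULL)
  for (site in SENSOR_SITES) {
    f <- paste0(name, "_", site, ".csv")
    write_stream(session$streams[[site]], file.path(dir, f))
    man$streams[[site]] <- f
  }
  fa <- paste0(name, "_annotations.csv")
  write_annotations(session$annotations, file.path(dir, fa))
  man$annotations <- fa
  if (!is.null(session$calibration)) {
    cal <- session$calibration
    man$calibration <- list(standing = list(), poses = list())
    for (site in names(cal$standing)) {
      f <- paste0(name, "_cal_standing_", site, ".csv")
      write_stream(cal$standing[[site]], file.path(dir, f))
      man$calibration$standing[[site]] <- f
    }
    for (i in seq_along(cal$poses)) {
      p <- cal$poses[[i]]
      entry <- list(nominal_angle = p$nominal_angle, streams = list())
      for (site in names(p$streams)) {
        f <- paste0(name, "_cal_pose", i, "_", site, ".csv")
        write_stream(p$streams[[site]], file.path(dir, f))
        entry$streams[[site]] <- f
      }
      man$calibration$poses[[i]] <- entry
    }
  }
  mp <- file.path(dir, paste0(name, "_session.yaml"))
  yaml::write_yaml(man, mp)
  invisible(mp)
}

#' Read a session back from its YAML manifest
#' @param manifest path to a `<name>_session.yaml` written by [write_session()].
#' @return a [gait_session()].
#' @export
read_session <- function(manifest) {
  man <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  streams <- lapply(stats::setNames(SENSOR_SITES, SENSOR_SITES), function(site) {
    f <- man$streams[[site]]
    if (is.null(f)) kg_stop(paste0("manifest missing ", site, " stream"),
                            "kneegait_io_error")
    read_stream(file.path(dir, f), site)
  })
  ann <- read_annotations(file.path(dir, man$annotations))
  cal <- NULL
  if (!is.null(man$calibration)) {
    standing <- lapply(man$calibration$standing, function(f)
      read_stream(file.path(dir, f), "pelvis"))
    for (site in names(standing)) standing[[site]]$site <- site
    poses <- lapply(man$calibration$poses, function(p) {
      st <- lapply(names(p$streams), function(site) {
        s <- read_stream(file.path(dir, p$streams[[site]]), "thigh")
        s$site <- site
        s
      })
      names(st) <- names(p$streams)
      list(nominal_angle = p$nominal_angle, streams = st)
    })
    cal <- calibration_set(standing, poses)
  }
  gait_session(man$subject_id, man$timepoint, man$side, streams, ann, cal)
}

# --- reports ------------------------------------------------------------

# decimal places per report column, matching the precision of the printed
# outcome tables (speeds 2 dp, angles whole degrees, times 2 dp)
report_digits_for <- function(nm) {
  if (grepl("flexion|angle|excursion|tilt|obliquity|lean", nm)) return(0L)
  if (grepl("cadence|count|n_|steps", nm)) return(1L)
  if (grepl("speed|length|time|duration|sit_to_stand|stand_to_sit|power|stability|symmetry|slope|tug", nm)) return(2L)
  2L
}

#' Write an analysis report deterministically
#'
#' Fixed column order (as given) and fixed rounding, half away from zero:
#' speeds and times to 2 decimals, angles to whole degrees. Identical input
#' yields byte-identical output.
#'
#' @param report data.frame of metrics (one row per session x activity) or a
#'   flat named list.
#' @param path output path; `.json` extension selects JSON, anything else CSV.
#' @return the rounded data.frame, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report)) report <- as.data.frame(report)
  out <- report
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      dg <- report_digits_for(nm)
      out[[nm]] <- round_half_away(out[[nm]], dg)
    }
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    txt <- out
    for (nm in names(txt)) if (is.numeric(txt[[nm]]))
      txt[[nm]] <- fmt_fixed(txt[[nm]], report_digits_for(nm))
    write.csv(txt, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(out)
}

#' Read a report back
#' @param path report file written by [write_report()].
#' @return data.frame.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path)
  }
}
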