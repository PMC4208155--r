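#' @importFrom stats approx median coef lm cor sd quantile
#' @importFrom utils read.csv write.csv head tail
NULL

DEG <- pi / 180
GRAVITY <- 9.81

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Round half away from zero
#'
#' Commercial rounding used for report output (base R rounds half to even).
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a number with a fixed decimal count, half away from zero
#' @keywords internal
fmt_fixed <- function(x, digits) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

# zero-phase Butterworth low-pass with edge padding (filtfilt start-up
# transients would otherwise corrupt interval boundaries)
smooth_lowpass <- function(x, rate, fc, order = 2) {
  n <- length(x)
  if (n < 12) return(x)
  np <- min(n - 1, round(rate))
  xp <- c(rep(x[1], np), x, rep(x[n], np))
  bf <- signal::butter(order, min(0.95, fc / (rate / 2)))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

kg_stop <- function(msg, class) {
  stop(structure(class = c(class, "kneegait_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

kg_log <- function(..., verbose = getOption("kneegait.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[kneegait] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
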