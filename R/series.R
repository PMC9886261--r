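#' Tri-axial acceleration series
#'
#' Container for one stream of trunk-worn accelerometer samples. Time is in
#' seconds since local midnight; files nominally cover 24 h but the device
#' clock may drift, so timestamps up to `86400 + slack` seconds are accepted
#' (default slack 1800 s, i.e. +/- 30 min).
#'
#' @param t Numeric vector, seconds since local midnight, monotone
#'   non-decreasing.
#' @param ax,ay,az Numeric vectors, per-axis acceleration in g. With the
#'   device worn on the trunk, `ax` is vertical when the wearer is upright.
#' @param fs_nominal Nominal sampling frequency in Hz (default 50).
#' @param slack_s Accepted overshoot past 86400 s (default 1800).
#' @return An object of class `accel_series`: a list with elements `t`,
#'   `ax`, `ay`, `az` and `fs_nominal`.
#' @examples
#' acc <- accel_series(t = c(0, 0.02), ax = c(1, 1), ay = c(0, 0), az = c(0, 0))
#' length(acc$t)
#' @export
accel_series <- function(t, ax, ay, az, fs_nominal = 50, slack_s = 1800) {
  n <- length(t)
  if (n == 0L) stop("empty-input error: accel series has no samples")
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("format error: t/ax/ay/az lengths differ")
  if (is.unsorted(t)) stop("ordering error: timestamps not monotone non-decreasing")
  if (any(t < 0) || any(t > 86400 + slack_s))
    stop("format error: timestamps outside [0, 86400 + slack]")
  rng <- range(abs(c(ax, ay, az)))
  if (rng[2] > 8) stop("format error: |acceleration| exceeds the 8 g sensor range")
  structure(list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), fs_nominal = fs_nominal),
            class = "accel_series")
}

#' Barometric pressure/temperature series
#'
#' @param t Numeric vector, seconds since local midnight.
#' @param p Atmospheric pressure in mbar; plausible range (800, 1100).
#' @param temp Temperature in kelvin (> 0).
#' @param fs_nominal Nominal sampling frequency in Hz (default 5).
#' @param slack_s Accepted overshoot past 86400 s (default 1800).
#' @return An object of class `baro_series`.
#' @export
baro_series <- function(t, p, temp, fs_nominal = 5, slack_s = 1800) {
  n <- length(t)
  if (n == 0L) stop("empty-input error: baro series has no samples")
  if (length(p) != n || length(temp) != n)
    stop("format error: t/p/temp lengths differ")
  if (is.unsorted(t)) stop("ordering error: timestamps not monotone non-decreasing")
  if (any(t < 0) || any(t > 86400 + slack_s))
    stop("format error: timestamps outside [0, 86400 + slack]")
  if (any(p <= 800) || any(p >= 1100))
    stop("format error: pressure outside the plausible (800, 1100) mbar range")
  if (any(temp <= 0)) stop("format error: non-positive temperature in kelvin")
  structure(list(t = as.numeric(t), p = as.numeric(p), temp = as.numeric(temp),
                 fs_nominal = fs_nominal),
            class = "baro_series")
}

#' One subject-day of sensor data
#'
#' Bundles the two sensor streams with subject metadata. The coverage
#' `duration_s` is the span of observed accelerometer time; feature
#' extraction refuses days with under four hours of coverage.
#'
#' @param subject_id Opaque subject identifier (string).
#' @param date Calendar date (`Date` or string parseable as one).
#' @param accel An [accel_series()].
#' @param baro A [baro_series()].
#' @param weight_kg Body weight in kg, or `NA` when unknown (energy
#'   expenditure is then only available weight-normalised).
#' @return An object of class `day_recording`.
#' @export
day_recording <- function(subject_id, date, accel, baro, weight_kg = NA_real_) {
  stopifnot(inherits(accel, "accel_series"), inherits(baro, "baro_series"))
  if (!is.na(weight_kg) && weight_kg <= 0)
    stop("parameter error: weight_kg must be positive")
  structure(list(subject_id = as.character(subject_id),
                 date = as.Date(date),
                 accel = accel, baro = baro,
                 weight_kg = as.numeric(weight_kg),
                 duration_s = diff(range(accel$t))),
            class = "day_recording")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples, t in [%.2f, %.2f] s, nominal %g Hz\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$fs_nominal))
  invisible(x)
}

#' @export
print.baro_series <- function(x, ...) {
  cat(sprintf("<baro_series> %d samples, t in [%.2f, %.2f] s, nominal %g Hz\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$fs_nominal))
  invisible(x)
}

#' @export
print.day_recording <- function(x, ...) {
  cat(sprintf("<day_recording> subject %s, %s: %d accel / %d baro samples, %.1f h coverage\n",
              x$subject_id, format(x$date), length(x$accel$t), length(x$baro$t),
              x$duration_s / 3600))
  invisible(x)
}
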