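#' Acceleration magnitude
#'
#' Elementwise Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` of a tri-axial
#' series; the basic quantity every downstream feature works on. At rest the
#' magnitude sits near 1 g (gravity), dips toward 0 g in airborne phases and
#' oscillates around 1 g during gait.
#'
#' @param accel An [accel_series()].
#' @return A list of class `magnitude_series` with elements `t`, `mag` (g)
#'   and `fs_nominal`.
#' @export
magnitude <- function(accel) {
  stopifnot(inherits(accel, "accel_series"))
  structure(list(t = accel$t,
                 mag = sqrt(accel$ax^2 + accel$ay^2 + accel$az^2),
                 fs_nominal = accel$fs_nominal),
            class = "magnitude_series")
}

#' Slope-limit filter for barometric pressure
#'
#' Removes sudden pressure spikes (door slams, gusts on the sensor port) by
#' clamping each sample-to-sample increment so that the filtered series never
#' changes faster than `max_slope_mbar_per_s`. The first sample passes
#' through unchanged; temperature is untouched. The default 0.5 mbar/s
#' corresponds to roughly 4 m/s of altitude change, far above lift speeds
#' (about 0.9 m/s), so genuine lift/stair ramps are preserved.
#'
#' @param baro A [baro_series()].
#' @param max_slope_mbar_per_s Positive slope bound.
#' @return A [baro_series()] with filtered pressure.
#' @export
slope_limit_filter <- function(baro, max_slope_mbar_per_s = 0.5) {
  stopifnot(inherits(baro, "baro_series"))
  if (max_slope_mbar_per_s <= 0)
    stop("parameter error: max_slope_mbar_per_s must be positive")
  p <- baro$p
  n <- length(p)
  if (n > 1L) {
    dt <- diff(baro$t)
    dt[dt <= 0] <- 1 / baro$fs_nominal
    bound <- max_slope_mbar_per_s * dt
    # recursive clamp: p'[i] = p'[i-1] + clip(p[i] - p'[i-1], +/- bound)
    p <- clamp_recursion(p, bound)
  }
  out <- baro
  out$p <- p
  out
}

clamp_recursion <- function(p, bound) {
  out <- p
  for (i in 2:length(p)) {
    step <- p[i] - out[i - 1]
    b <- bound[i - 1]
    out[i] <- out[i - 1] + max(-b, min(b, step))
  }
  out
}

#' Barometric altitude on a one-second grid
#'
#' Converts filtered pressure and temperature to altitude with the
#' barometric formula `H = T/0.0065 * (1 - (P'/1013.25)^0.19)` (H in m, T in
#' K, P' in mbar), then averages the samples within each second of the day.
#' Seconds with no barometric samples are left `NA` (gaps are not
#' interpolated when longer than `max_gap_s`).
#'
#' @param baro_filtered A [baro_series()], normally the output of
#'   [slope_limit_filter()].
#' @param max_gap_s Longest gap (s) bridged by linear interpolation
#'   (default 3).
#' @return A list of class `altitude_series`: `t` (integer seconds, start of
#'   each second from floor(min t) to floor(max t)), `h` (m, `NA` in gaps)
#'   and `p_filtered` (mean filtered pressure per second).
#' @export
altitude <- function(baro_filtered, max_gap_s = 3) {
  b <- baro_filtered
  stopifnot(inherits(b, "baro_series"))
  if (any(b$p <= 0)) stop("domain error: non-positive pressure")
  h_sample <- barometric_height(b$p, b$temp)
  sec <- floor(b$t)
  grid <- seq.int(sec[1], sec[length(sec)])
  idx <- sec - sec[1] + 1L
  cnt <- tabulate(idx, nbins = length(grid))
  h <- rowsum_vec(h_sample, idx, length(grid)) / ifelse(cnt == 0, NA, cnt)
  p <- rowsum_vec(b$p, idx, length(grid)) / ifelse(cnt == 0, NA, cnt)
  # bridge short gaps only
  h <- fill_short_gaps(grid, h, max_gap_s)
  p <- fill_short_gaps(grid, p, max_gap_s)
  structure(list(t = grid, h = h, p_filtered = p), class = "altitude_series")
}

barometric_height <- function(p_mbar, temp_k) {
  temp_k / 0.0065 * (1 - (p_mbar / 1013.25)^0.19)
}

rowsum_vec <- function(x, group, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

fill_short_gaps <- function(t, x, max_gap_s) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths <= max_gap_s)) {
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    if (i0 >= 1L && i1 <= length(x))
      x[starts[k]:ends[k]] <- stats::approx(c(t[i0], t[i1]), c(x[i0], x[i1]),
                                            xout = t[starts[k]:ends[k]])$y
  }
  x
}
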