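#' Sleep calmness (G2)
#'
#' "Night mode" covers 22:00 to 08:00. The three acceleration components of
#' the night span are decomposed into 5-second fragments with 80% overlap
#' (1-s hop). A fragment is *silent* when every axis has a low standard
#' deviation (< 0.03 g) and a low range (< 0.1 g). Maximal runs of
#' consecutive silent fragments whose duration `S` exceeds five minutes are
#' *sleep cycles*; the sleeping time SpT is the sum of cycle lengths, and
#' the lying time LyT is the span from the start of the first cycle to the
#' end of the last one restricted to seconds classified as lying. Then
#' `G2 = 100 * SpT / LyT`, or `NA` when no cycle is found (for example a
#' night of continuous tossing).
#'
#' Within a single 24-h file the night is assembled from the two within-file
#' halves (22:00-24:00 followed by 00:00-08:00 mapped onto one night clock);
#' this treats the morning block as the same subject-night, an approximation
#' flagged in the result.
#'
#' @param accel An [accel_series()] covering (part of) the day.
#' @param night_start_s,night_end_s Night-mode span in seconds of day time
#'   (defaults 79200 = 22:00 and 28800 = 08:00).
#' @param sd_threshold_g,range_threshold_g Silence thresholds (defaults
#'   0.03 g and 0.1 g).
#' @param fragment_s Fragment length in seconds (default 5).
#' @param overlap Fragment overlap fraction (default 0.8, i.e. 1-s hop).
#' @param min_cycle_s Minimum sleep-cycle duration in seconds (default 300).
#' @return A list with `G2` (percent, `NA` when undefined), `SpT_s`,
#'   `LyT_s`, `cycles` (data frame of cycle start/end on the night clock,
#'   seconds after 22:00) and `approx_night` (TRUE when assembled within one
#'   file).
#' @export
sleep_calmness <- function(accel, night_start_s = 79200, night_end_s = 28800,
                           sd_threshold_g = 0.03, range_threshold_g = 0.1,
                           fragment_s = 5, overlap = 0.8, min_cycle_s = 300) {
  stopifnot(inherits(accel, "accel_series"))
  fs <- accel$fs_nominal
  # map to a night clock: 0 at night_start; spans crossing midnight wrap
  nt <- rep(NA_real_, length(accel$t))
  if (night_start_s < night_end_s) {
    inside <- accel$t >= night_start_s & accel$t < night_end_s
    nt[inside] <- accel$t[inside] - night_start_s
  } else {
    evening <- accel$t >= night_start_s
    morning <- accel$t < night_end_s
    nt[evening] <- accel$t[evening] - night_start_s
    nt[morning] <- accel$t[morning] + (86400 - night_start_s)
  }
  keep <- !is.na(nt)
  if (!any(keep))
    return(list(G2 = NA_real_, SpT_s = 0, LyT_s = 0,
                cycles = empty_cycles(), approx_night = TRUE))
  ord <- order(nt[keep])
  idx <- which(keep)[ord]
  ax <- accel$ax[idx]; ay <- accel$ay[idx]; az <- accel$az[idx]
  n_sec <- length(idx) %/% fs
  if (n_sec < fragment_s)
    return(list(G2 = NA_real_, SpT_s = 0, LyT_s = 0,
                cycles = empty_cycles(), approx_night = TRUE))
  night_t0 <- min(nt[keep])

  stats <- lapply(list(ax, ay, az), per_second_stats, fs = fs)
  hop_sec <- max(1L, round(fragment_s * (1 - overlap)))
  silent <- rep(TRUE, n_sec - fragment_s + 1L)
  for (s in stats) {
    f <- fragment_stats(s, fragment_s)
    silent <- silent & (f$sd < sd_threshold_g) & (f$range < range_threshold_g)
  }
  frag_starts <- seq.int(1L, length(silent), by = hop_sec)
  silent <- silent[frag_starts]

  # per-second lying flag from mean orientation
  lying <- posture_from_means(vapply(stats, `[[`, numeric(n_sec), "mean")[, 1],
                              vapply(stats, `[[`, numeric(n_sec), "mean")[, 2],
                              vapply(stats, `[[`, numeric(n_sec), "mean")[, 3]) == "lying"

  r <- rle(silent)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  dur <- (r$lengths - 1L) * hop_sec + fragment_s
  is_cycle <- r$values & dur > min_cycle_s
  if (!any(is_cycle))
    return(list(G2 = NA_real_, SpT_s = 0, LyT_s = 0,
                cycles = empty_cycles(), approx_night = TRUE))
  cyc_start <- (frag_starts[starts[is_cycle]] - 1L) + night_t0
  cyc_end <- cyc_start + dur[is_cycle]
  spt <- sum(dur[is_cycle])
  span_sec <- seq.int(cyc_start[1] - night_t0 + 1L,
                      min(n_sec, cyc_end[length(cyc_end)] - night_t0))
  lyt <- sum(lying[span_sec])
  g2 <- if (lyt > 0) 100 * spt / lyt else NA_real_
  list(G2 = g2, SpT_s = spt, LyT_s = lyt,
       cycles = data.frame(start_s = cyc_start, end_s = cyc_end),
       approx_night = TRUE)
}

empty_cycles <- function() data.frame(start_s = numeric(0), end_s = numeric(0))

# per-second (fs-sample) mean, sum, sum of squares, min, max
per_second_stats <- function(x, fs) {
  m <- window_matrix(x, fs, 1)
  list(mean = colMeans(m),
       sum = colSums(m),
       sumsq = colSums(m * m),
       min = col_min(m),
       max = col_max(m),
       n = nrow(m))
}

# aggregate consecutive seconds into fragments of `len` seconds (hop 1 s)
fragment_stats <- function(s, len) {
  k <- length(s$sum) - len + 1L
  roll <- function(v) {
    c0 <- cumsum(v)
    c0[len:length(v)] - c(0, c0)[len:length(v) - len + 1L]
  }
  fsum <- roll(s$sum); fss <- roll(s$sumsq)
  n <- s$n * len
  mu <- fsum / n
  sdv <- sqrt(pmax(0, fss / n - mu * mu))
  shift <- function(v, j) v[seq.int(1L + j, length(v) - len + 1L + j)]
  fmin <- Reduce(pmin, lapply(0:(len - 1L), shift, v = s$min))
  fmax <- Reduce(pmax, lapply(0:(len - 1L), shift, v = s$max))
  list(sd = sdv, range = fmax - fmin, k = k)
}
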