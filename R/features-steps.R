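#' Step count (G3)
#'
#' Steps appear as one dominant peak per step in the acceleration magnitude.
#' Peaks are detected on the band-passed (0.5-5 Hz Butterworth, zero-phase)
#' magnitude as local maxima exceeding `prominence_g` above the band-passed
#' baseline, with a minimum spacing of `min_spacing_s`, and are counted only
#' inside windows where the wearer is both standing (upright posture) and
#' moving (active window). Zero steps is a valid result.
#'
#' @param mag A `magnitude_series`.
#' @param windows Window data frame from [activity_windows()] (with
#'   `active` and `posture` columns).
#' @param prominence_g Minimum peak height above the zero-centred band-passed
#'   baseline (default 0.05 g).
#' @param min_spacing_s Minimum peak spacing in seconds (default 0.3, just
#'   above the physiological 250 ms bound between gait events).
#' @param band_hz Band-pass corner frequencies (default `c(0.5, 5)`).
#' @return A list with `G3` (integer step count) and `peak_t` (times of the
#'   counted peaks).
#' @export
count_steps <- function(mag, windows, prominence_g = 0.05, min_spacing_s = 0.3,
                        band_hz = c(0.5, 5)) {
  stopifnot(inherits(mag, "magnitude_series"))
  fs <- mag$fs_nominal
  qual <- windows$active & windows$posture == "upright"
  if (!any(qual)) return(list(G3 = 0L, peak_t = numeric(0)))
  bp <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, mag$mag - mean(mag$mag))
  min_gap <- round(min_spacing_s * fs)
  total <- 0L
  peak_t <- vector("list", sum(qual))
  j <- 0L
  for (i in which(qual)) {
    seg <- x[windows$start_idx[i]:windows$end_idx[i]]
    pk <- find_peaks(seg, height = prominence_g, min_gap = min_gap)
    total <- total + length(pk)
    j <- j + 1L
    peak_t[[j]] <- mag$t[windows$start_idx[i] + pk - 1L]
  }
  list(G3 = total, peak_t = unlist(peak_t))
}

# local maxima above `height`, thinned so surviving peaks are >= min_gap
# samples apart (greedy, highest first)
find_peaks <- function(x, height, min_gap) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > height) + 1L
  if (length(cand) <= 1L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_gap)) taken <- c(taken, p)
  }
  sort(taken)
}
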