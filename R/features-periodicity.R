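#' Movement periodicity rate (G4) and gait period (G5)
#'
#' For every active 30-s window the normalised (biased, unit at lag zero)
#' autocorrelation of the demeaned magnitude is computed. Peaks above
#' `peak_height` at positive lags, separated by at least `min_sep_s`, are
#' detected; a window counts as *periodic* when at least `min_peaks` peaks
#' are present. With `T` periodic windows over an observation period of `D`
#' seconds, the periodicity rate is `G4 = 100 * 30 * T / D` (percent of the
#' covered day spent in periodic movement) and the period is
#' `G5 = mean over periodic windows of the mean peak spacing` in seconds
#' (lag counts divided by the sampling frequency). `G5` is `NA` when no
#' window is periodic.
#'
#' @param mag A `magnitude_series`.
#' @param windows Window data frame from [activity_windows()].
#' @param D_s Observation period in seconds (actual coverage).
#' @param peak_height Autocorrelation peak threshold (default 0.3).
#' @param min_sep_s Minimum peak separation in seconds (default 0.25).
#' @param min_peaks Minimum number of peaks for a periodic window (default 3).
#' @param max_lag_s Longest lag inspected (default 10 s, which accommodates
#'   at least three peaks for periods up to ~3.3 s).
#' @return A list with `G4`, `G5`, `T` (number of periodic windows),
#'   `periodic` (logical per window) and `period_s` (per-window mean peak
#'   spacing, `NA` for non-periodic windows).
#' @export
periodicity <- function(mag, windows, D_s, peak_height = 0.3,
                        min_sep_s = 0.25, min_peaks = 3, max_lag_s = 10) {
  stopifnot(inherits(mag, "magnitude_series"))
  if (is.null(D_s) || !is.finite(D_s) || D_s <= 0)
    stop("insufficient-data error: observation period D is zero")
  fs <- mag$fs_nominal
  act <- which(windows$active)
  periodic <- rep(FALSE, nrow(windows))
  period_s <- rep(NA_real_, nrow(windows))
  if (length(act)) {
    win_n <- windows$end_idx[1] - windows$start_idx[1] + 1L
    max_lag <- min(win_n - 1L, round(max_lag_s * fs))
    seg <- matrix(0, nrow = win_n, ncol = length(act))
    for (k in seq_along(act)) {
      i <- act[k]
      seg[, k] <- mag$mag[windows$start_idx[i]:windows$end_idx[i]]
    }
    ac <- batch_autocorr(seg, max_lag)
    min_gap <- round(min_sep_s * fs)
    for (k in seq_along(act)) {
      pk <- find_peaks(ac[, k], height = peak_height, min_gap = min_gap)
      # the minimum separation also applies against the lag-0 peak, which
      # discards sub-250 ms junk maxima on the autocorrelation shoulder
      pk <- pk[pk - 1L >= min_gap]
      if (length(pk) >= min_peaks) {
        periodic[act[k]] <- TRUE
        period_s[act[k]] <- mean(diff(pk - 1L)) / fs
      }
    }
  }
  T_n <- sum(periodic)
  list(G4 = 100 * 30 * T_n / D_s,
       G5 = if (T_n > 0) mean(period_s[periodic]) else NA_real_,
       T = T_n, periodic = periodic, period_s = period_s)
}

# biased autocorrelation of each demeaned column, normalised to 1 at lag 0;
# FFT-based so a whole day of active windows is one batched operation.
# Row r of the result is lag r-1.
batch_autocorr <- function(seg, max_lag) {
  n <- nrow(seg)
  seg <- sweep(seg, 2, colMeans(seg))
  nfft <- 2^ceiling(log2(2 * n))
  pad <- rbind(seg, matrix(0, nfft - n, ncol(seg)))
  f <- stats::mvfft(pad)
  ac <- Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L), , drop = FALSE]
  lag0 <- ac[1, ]
  lag0[lag0 == 0] <- 1
  sweep(ac, 2, lag0, "/")
}

#' Walking speed from stride length and gait period
#'
#' The extracted period `G5` stands in for the stride time of gait, so a
#' wearer with stride length `stride_m` walks at `stride_m / T_p` m/s; for
#' example a 0.8 m stride at a 0.8 s period gives 1 m/s.
#'
#' @param stride_m Stride length in meters (> 0).
#' @param T_p Gait period in seconds (> 0).
#' @return Walking speed in m/s.
#' @examples
#' estimate_walking_speed(0.8, 0.8)  # 1 m/s
#' @export
estimate_walking_speed <- function(stride_m, T_p) {
  if (any(stride_m <= 0) || any(T_p <= 0))
    stop("parameter error: stride_m and T_p must be positive")
  stride_m / T_p
}
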