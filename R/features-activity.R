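#' Activity windows and activity rate (G1)
#'
#' Splits the magnitude series into non-overlapping 30-s windows; each
#' window is demeaned and its root-mean-square computed. Windows whose rms
#' exceeds `rms_threshold_g` (default 0.03 g, the "3%" movement threshold in
#' native g units) are labeled active. The activity rate is
#' `G1 = K_A / K`, the fraction of active windows.
#'
#' @param mag A `magnitude_series` from [magnitude()].
#' @param accel The parent [accel_series()]; when supplied, each window also
#'   gets a posture label from the mean axis orientation.
#' @param window_s Window length in seconds (default 30).
#' @param rms_threshold_g Active threshold on the demeaned rms (default 0.03).
#' @return A list with `windows` (data frame: `start_s`, `length_s`, `rms`,
#'   `sd` (= rms of the demeaned window, the intensity measure used for MET
#'   banding), `active`, `posture`), `G1`, `K`, `K_A`.
#' @export
activity_windows <- function(mag, accel = NULL, window_s = 30,
                             rms_threshold_g = 0.03) {
  stopifnot(inherits(mag, "magnitude_series"))
  fs <- mag$fs_nominal
  w <- partition_windows(length(mag$mag), fs, window_s)
  if (nrow(w) == 0L)
    stop("insufficient-data error: day too short for a single window")
  m <- window_matrix(mag$mag, fs, window_s)
  sdv <- col_sd_pop(m)          # rms of the demeaned window == population SD
  w$rms <- sdv
  w$sd <- sdv
  w$active <- sdv > rms_threshold_g
  w$start_s <- mag$t[w$start_idx]
  if (!is.null(accel)) {
    mx <- colMeans(window_matrix(accel$ax, fs, window_s))
    my <- colMeans(window_matrix(accel$ay, fs, window_s))
    mz <- colMeans(window_matrix(accel$az, fs, window_s))
    w$posture <- posture_from_means(mx, my, mz)
  } else {
    w$posture <- rep("unknown", nrow(w))
  }
  list(windows = w, G1 = mean(w$active), K = nrow(w), K_A = sum(w$active))
}

#' Posture from mean acceleration orientation
#'
#' During low movement the mean of each axis reflects the gravity direction:
#' with the device on the trunk, `ax` is vertical when upright. A window is
#' upright (standing/sitting) when `|mean ax| >= 0.7` g, lying when
#' `|mean ax| <= 0.4` g while `|mean ay|` or `|mean az|` carries gravity
#' (>= 0.7 g), and unknown otherwise.
#'
#' @param accel_window An [accel_series()] slice (any length >= 1).
#' @return One of `"upright"`, `"lying"`, `"unknown"`.
#' @export
classify_posture <- function(accel_window) {
  stopifnot(inherits(accel_window, "accel_series"))
  if (length(accel_window$t) == 0L) stop("empty-input error: empty window")
  posture_from_means(mean(accel_window$ax), mean(accel_window$ay),
                     mean(accel_window$az))
}

posture_from_means <- function(mx, my, mz) {
  out <- rep("unknown", length(mx))
  out[abs(mx) >= 0.7] <- "upright"
  out[abs(mx) <= 0.4 & (abs(my) >= 0.7 | abs(mz) >= 0.7)] <- "lying"
  out
}
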