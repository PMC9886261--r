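#' Partition a sampled series into fixed-length windows
#'
#' Windows tile the series with hop `window_s * (1 - overlap_fraction)`;
#' a trailing partial window shorter than `window_s` is discarded (never
#' zero-padded, which would bias rms/SD statistics).
#'
#' @param n_samples Length of the parent series in samples.
#' @param fs Sampling frequency in Hz.
#' @param window_s Window length in seconds.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @return A data frame with one row per window: `start_s`, `length_s`,
#'   `start_idx`, `end_idx` (1-based, inclusive sample indices).
#' @examples
#' nrow(partition_windows(3000, fs = 50, window_s = 30))             # 2
#' nrow(partition_windows(250, fs = 50, window_s = 5, overlap = 0.8)) # 1
#' @export
partition_windows <- function(n_samples, fs, window_s, overlap_fraction = 0) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("parameter error: overlap_fraction must be in [0, 1)")
  win_n <- round(window_s * fs)
  if (win_n < 1) stop("parameter error: window_s * fs must be >= 1")
  hop_n <- max(1L, round(win_n * (1 - overlap_fraction)))
  starts <- seq.int(0L, by = hop_n, length.out = max(0L, (n_samples - win_n) %/% hop_n + 1L))
  if (n_samples < win_n) starts <- integer(0)
  data.frame(start_s = starts / fs,
             length_s = rep(window_s, length(starts)),
             start_idx = starts + 1L,
             end_idx = starts + win_n)
}

# Per-window column views: reshape x (using the first K*win full samples of the
# non-overlapping partition) into a win x K matrix. Only valid for overlap 0.
window_matrix <- function(x, fs, window_s) {
  win <- round(window_s * fs)
  k <- length(x) %/% win
  if (k == 0L) return(matrix(numeric(0), nrow = win, ncol = 0))
  matrix(x[seq_len(k * win)], nrow = win, ncol = k)
}

# column max/min of a matrix without apply() overhead
col_max <- function(m) {
  if (ncol(m) == 0) return(numeric(0))
  as.vector(do.call(pmax, asplit(m, 1)))
}
col_min <- function(m) {
  if (ncol(m) == 0) return(numeric(0))
  as.vector(do.call(pmin, asplit(m, 1)))
}

col_sd_pop <- function(m) {
  # population SD per column
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(0, colMeans(m * m) - mu * mu))
}
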