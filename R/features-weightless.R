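#' Weightlessness time (G6)
#'
#' In airborne phases (jumping, jogging) gravity is cancelled by inertial
#' force and the magnitude drops toward 0 g. G6 is the total duration in
#' seconds of maximal intervals where `mag < threshold_g` lasting at least
#' `min_len_s`.
#'
#' @param mag A `magnitude_series`.
#' @param threshold_g Weightlessness threshold (default 0.3 g).
#' @param min_len_s Minimum interval length (default 0.04 s, i.e. two
#'   samples at 50 Hz).
#' @return A list with `G6` (seconds) and `episodes` (data frame of
#'   `start_s`, `end_s`, `length_s`).
#' @export
weightlessness <- function(mag, threshold_g = 0.3, min_len_s = 0.04) {
  stopifnot(inherits(mag, "magnitude_series"))
  fs <- mag$fs_nominal
  low <- mag$mag < threshold_g
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= min_len_s)
  len_s <- r$lengths[keep] / fs
  episodes <- data.frame(start_s = mag$t[starts[keep]],
                         end_s = mag$t[starts[keep]] + len_s,
                         length_s = len_s)
  list(G6 = sum(len_s), episodes = episodes)
}
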