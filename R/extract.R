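#' Feature-extraction configuration
#'
#' All thresholds of the daily-feature extractor with their defaults: the
#' "3%" movement thresholds are interpreted in native g units (0.03 g), and
#' every band is configurable.
#'
#' @param window_s Activity window length (s).
#' @param rms_threshold_g Active-window rms threshold (g).
#' @param sleep Named list of sleep-calmness settings (see
#'   [sleep_calmness()]).
#' @param steps Named list of step-detector settings (see [count_steps()]).
#' @param periodicity Named list of periodicity settings (see
#'   [periodicity()]).
#' @param weightless Named list: `threshold_g`, `min_len_s`.
#' @param cia Named list of change-in-altitude settings (see
#'   [change_in_altitude()]).
#' @param max_slope_mbar_per_s Slope-limit filter bound.
#' @param met A [met_table()].
#' @param normalize_energy Report G9 in kcal/kg (default TRUE).
#' @return A list of class `af_config`.
#' @export
af_config <- function(window_s = 30, rms_threshold_g = 0.03,
                      sleep = list(), steps = list(), periodicity = list(),
                      weightless = list(), cia = list(),
                      max_slope_mbar_per_s = 0.5, met = met_table(),
                      normalize_energy = TRUE) {
  structure(list(window_s = window_s, rms_threshold_g = rms_threshold_g,
                 sleep = sleep, steps = steps, periodicity = periodicity,
                 weightless = weightless, cia = cia,
                 max_slope_mbar_per_s = max_slope_mbar_per_s,
                 met = met, normalize_energy = normalize_energy),
            class = "af_config")
}

#' Extract the nine daily features from one recording
#'
#' Orchestrates the full per-day pipeline: magnitude, 30-s activity windows
#' and posture (G1), overnight sleep calmness (G2), step counting (G3),
#' autocorrelation periodicity (G4/G5), weightlessness (G6), slope-limited
#' barometric altitude and lift/stair episodes (G7/G8), and MET-based
#' energy expenditure over the labeled windows (G9).
#'
#' Days with under four hours of accelerometer coverage yield an
#' all-missing feature vector with `reason = "insufficient_coverage"`. If
#' the observed median sampling interval deviates from the nominal rate by
#' more than 10%, the acceleration is linearly resampled onto the nominal
#' grid with a warning.
#'
#' @param rec A [day_recording()].
#' @param config An [af_config()].
#' @return A list with `features` (one-row data frame:
#'   `subject,date,G1..G9,label`), `episodes` (data frame episode log) and
#'   `reason` (`NA` or a skip code).
#' @export
extract_day <- function(rec, config = af_config()) {
  stopifnot(inherits(rec, "day_recording"))
  if (rec$duration_s < 4 * 3600) {
    return(list(features = feature_row(rec$subject_id, rec$date),
                episodes = empty_episodes(),
                reason = "insufficient_coverage"))
  }
  accel <- maybe_resample(rec$accel)
  mag <- magnitude(accel)
  aw <- activity_windows(mag, accel, window_s = config$window_s,
                         rms_threshold_g = config$rms_threshold_g)
  win <- aw$windows

  slp <- do.call(sleep_calmness, c(list(accel = accel), config$sleep))
  stp <- do.call(count_steps, c(list(mag = mag, windows = win), config$steps))
  per <- do.call(periodicity, c(list(mag = mag, windows = win,
                                     D_s = rec$duration_s), config$periodicity))
  wlt <- do.call(weightlessness, c(list(mag = mag), config$weightless))

  baro_f <- slope_limit_filter(rec$baro, config$max_slope_mbar_per_s)
  alt <- altitude(baro_f)
  cia <- do.call(change_in_altitude, c(list(alt = alt, windows = win),
                                       config$cia))

  segments <- window_segments(win, per$periodic, wlt$episodes, config$window_s)
  ee <- energy_expenditure(segments, met = config$met,
                           weight_kg = rec$weight_kg,
                           normalize = config$normalize_energy)

  feats <- feature_row(rec$subject_id, rec$date,
                       G1 = aw$G1, G2 = slp$G2, G3 = stp$G3,
                       G4 = per$G4, G5 = per$G5, G6 = wlt$G6,
                       G7 = cia$G7, G8 = cia$G8, G9 = ee$G9)
  list(features = feats,
       episodes = build_episode_log(win, slp, per, wlt, cia),
       reason = NA_character_)
}

feature_row <- function(subject, date, G1 = NA_real_, G2 = NA_real_,
                        G3 = NA_real_, G4 = NA_real_, G5 = NA_real_,
                        G6 = NA_real_, G7 = NA_real_, G8 = NA_real_,
                        G9 = NA_real_, label = NA_character_) {
  data.frame(subject = subject, date = as.character(as.Date(date)),
             G1 = G1, G2 = G2, G3 = as.numeric(G3), G4 = G4, G5 = G5,
             G6 = G6, G7 = as.numeric(G7), G8 = as.numeric(G8), G9 = G9,
             label = label, stringsAsFactors = FALSE)
}

maybe_resample <- function(accel) {
  dt <- stats::median(diff(accel$t))
  nominal <- 1 / accel$fs_nominal
  if (!is.finite(dt) || abs(dt - nominal) / nominal <= 0.1) return(accel)
  warning(sprintf("median sampling interval %.4f s deviates from nominal %.4f s by >10%%; resampling",
                  dt, nominal))
  grid <- seq(accel$t[1], accel$t[length(accel$t)], by = nominal)
  accel_series(grid,
               stats::approx(accel$t, accel$ax, grid)$y,
               stats::approx(accel$t, accel$ay, grid)$y,
               stats::approx(accel$t, accel$az, grid)$y,
               fs_nominal = accel$fs_nominal)
}

window_segments <- function(win, periodic, wl_episodes, window_s) {
  type <- rep(NA_character_, nrow(win))
  type[win$active] <- "light"
  type[periodic] <- "periodic"
  if (nrow(wl_episodes)) {
    for (i in seq_len(nrow(wl_episodes))) {
      hit <- win$start_s < wl_episodes$end_s[i] &
        (win$start_s + win$length_s) > wl_episodes$start_s[i]
      type[hit] <- "weightless"
    }
  }
  data.frame(state = ifelse(win$active, "active", "inactive"),
             type = type, sigma = win$sd,
             duration_h = win$length_s / 3600)
}

empty_episodes <- function() {
  data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0),
             value = numeric(0), stringsAsFactors = FALSE)
}

build_episode_log <- function(win, slp, per, wlt, cia) {
  ep <- list()
  add <- function(kind, start_s, end_s, value = NA_real_) {
    if (length(start_s))
      ep[[length(ep) + 1L]] <<- data.frame(kind = kind, start_s = start_s,
                                           end_s = end_s, value = value,
                                           stringsAsFactors = FALSE)
  }
  runs <- rle(win$active)
  re <- cumsum(runs$lengths); rs <- re - runs$lengths + 1L
  add(ifelse(runs$values, "active", "inactive"),
      win$start_s[rs], win$start_s[re] + win$length_s[re])
  if (nrow(slp$cycles))
    add("sleep_cycle", slp$cycles$start_s, slp$cycles$end_s)
  if (any(per$periodic)) {
    pr <- rle(per$periodic)
    pe <- cumsum(pr$lengths); ps <- pe - pr$lengths + 1L
    keep <- pr$values
    add("periodic_bout", win$start_s[ps[keep]],
        win$start_s[pe[keep]] + win$length_s[pe[keep]],
        value = vapply(which(keep), function(k)
          mean(per$period_s[ps[k]:pe[k]]), numeric(1)))
  }
  if (nrow(wlt$episodes))
    add("weightless", wlt$episodes$start_s, wlt$episodes$end_s,
        wlt$episodes$length_s)
  if (nrow(cia$episodes))
    add(cia$episodes$kind, cia$episodes$start_s, cia$episodes$end_s,
        cia$episodes$dH_m)
  if (!length(ep)) return(empty_episodes())
  out <- do.call(rbind, ep)
  out[order(out$start_s), ]
}

#' Write an episode log as JSON
#'
#' @param episodes Episode data frame from [extract_day()].
#' @param path Output path.
#' @export
write_episode_log <- function(episodes, path) {
  jsonlite::write_json(episodes, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
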