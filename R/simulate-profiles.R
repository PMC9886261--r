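#' Synthetic subject profile
#'
#' Controls every phenomenological parameter of the signal-level day
#' generator: gait cadence and per-step amplitude, daily step and walking
#' volumes, the overall activity rate, barometric event rates (lifts and
#' stair episodes per day), nocturnal agitation, and day-to-day
#' variability. The bundled [frail_profile()] and [robust_profile()]
#' defaults encode the study conditions the package models: frail
#' octogenarians walk little (about 1000 steps/day) with a long gait period
#' (about 1.9 s), practically never take the stairs, and show a low
#' periodicity rate, while robust peers take about 4700 steps/day at a
#' 1.18 s period and use stairs daily.
#'
#' @param label `"frail"` or `"robust"`.
#' @param cadence_hz Step rate during continuous gait (steps/s, in
#'   `[0.5, 3]`); the gait period is `1/cadence_hz`.
#' @param step_amplitude_g Oscillation amplitude of continuous gait (g,
#'   in `(0, 1]`); sized so the magnitude SD of a gait window falls in the
#'   moderate MET band.
#' @param burst_amplitude_g Amplitude of short non-periodic walking bursts.
#' @param steps_per_day Target daily step count (before day-to-day jitter).
#' @param periodic_windows_per_day Number of full 30-s continuous-gait
#'   windows per day (sets the periodicity rate).
#' @param activity_rate Target fraction of active 30-s windows.
#' @param stairs_per_day,lifts_per_day Poisson means of daily episode
#'   counts.
#' @param agitations_per_night Poisson mean of nocturnal movement
#'   interruptions.
#' @param weight_kg Body weight.
#' @param day_cv Day-to-day lognormal coefficient of variation applied to
#'   walking volume.
#' @param jumps Optional list `list(count =, len_s =)` of airborne
#'   (weightless) intervals to inject into one daytime window.
#' @param pressure_spikes_per_day Poisson mean of single-sample pressure
#'   spikes (door slams) injected away from lift/stair ramps.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(label = c("robust", "frail"),
                            cadence_hz = 0.85, step_amplitude_g = 0.22,
                            burst_amplitude_g = 0.15,
                            steps_per_day = 4663,
                            periodic_windows_per_day = 100,
                            activity_rate = 0.20,
                            stairs_per_day = 1.41, lifts_per_day = 1.58,
                            agitations_per_night = 3,
                            weight_kg = 63, day_cv = 0.15,
                            jumps = NULL, pressure_spikes_per_day = 8) {
  label <- match.arg(label)
  if (cadence_hz < 0.5 || cadence_hz > 3)
    stop("parameter error: cadence_hz must be in [0.5, 3]")
  if (step_amplitude_g <= 0 || step_amplitude_g > 1)
    stop("parameter error: step_amplitude_g must be in (0, 1]")
  rates <- c(steps_per_day, periodic_windows_per_day, activity_rate,
             stairs_per_day, lifts_per_day, agitations_per_night,
             pressure_spikes_per_day)
  if (any(rates < 0)) stop("parameter error: rates must be >= 0")
  structure(as.list(environment()), class = "subject_profile")
}

#' @rdname subject_profile
#' @param ... Overrides passed to [subject_profile()].
#' @export
frail_profile <- function(...) {
  args <- list(label = "frail", cadence_hz = 1 / 1.9,
               step_amplitude_g = 0.18, burst_amplitude_g = 0.12,
               steps_per_day = 1019, periodic_windows_per_day = 7,
               activity_rate = 0.145, stairs_per_day = 0.02,
               lifts_per_day = 0.98, agitations_per_night = 6)
  over <- list(...)
  args[names(over)] <- over
  do.call(subject_profile, args)
}

#' @rdname subject_profile
#' @export
robust_profile <- function(...) {
  args <- list(label = "robust", cadence_hz = 1 / 1.18,
               step_amplitude_g = 0.22, burst_amplitude_g = 0.15,
               steps_per_day = 4663, periodic_windows_per_day = 100,
               activity_rate = 0.20, stairs_per_day = 1.41,
               lifts_per_day = 1.58, agitations_per_night = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(subject_profile, args)
}
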