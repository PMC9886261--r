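#' Cohort calibration: frail vs robust subject-mean distributions
#'
#' Per-feature distribution families for the subject-level means of the two
#' groups, chosen once from the group statistics the package models
#' (means, SDs and quartiles): positively skewed count-like features
#' (steps, periodicity rate, lift and stair frequency) are lognormal with
#' matched mean/SD; roughly symmetric percentages (activity rate, sleep
#' calmness, energy expenditure) are truncated normal; the gait period is
#' normal for robust subjects (1.18 +/- 0.04 s) and a shifted gamma
#' (1.35 s floor) for frail ones, whose quartiles (1.5-2.25 s) never reach
#' robust values; weightlessness is identically zero in both groups.
#'
#' @return Nested list `list(frail = ..., robust = ...)` of per-feature
#'   distribution specs.
#' @export
cohort_calibration <- function() {
  # min/max bound each draw to a physically plausible range compatible
  # with the group quartiles (a frail nursing-home faller does not walk
  # 8000+ steps/day; a robust community-dweller does not walk 500)
  list(
    frail = list(
      G1 = list(dist = "norm", mean = 0.145, sd = 0.048, min = 0.01, max = 0.9),
      G2 = list(dist = "norm", mean = 75.4, sd = 10.5, min = 0, max = 100),
      G3 = list(dist = "lnorm", mean = 1019, sd = 939, min = 250, max = 3500),
      G4 = list(dist = "lnorm", mean = 0.23, sd = 0.30, min = 0, max = 1.0),
      G5 = list(dist = "shiftgamma", shift = 1.35, mean = 0.55, sd = 0.63,
                max = 3.2),
      G6 = list(dist = "const", value = 0),
      G7 = list(dist = "lnorm", mean = 0.98, sd = 0.92, min = 0, max = 4),
      G8 = list(dist = "lnorm", mean = 0.02, sd = 0.05, min = 0, max = 0.2),
      G9 = list(dist = "norm", mean = 19.7, sd = 2.0, min = 14, max = 23)),
    robust = list(
      G1 = list(dist = "norm", mean = 0.20, sd = 0.057, min = 0.01, max = 0.9),
      G2 = list(dist = "norm", mean = 88.2, sd = 10.7, min = 0, max = 100),
      G3 = list(dist = "lnorm", mean = 4663, sd = 2036, min = 2000, max = 11000),
      G4 = list(dist = "lnorm", mean = 3.5, sd = 5.0, min = 0.8, max = 18),
      G5 = list(dist = "norm", mean = 1.18, sd = 0.04, min = 1.05, max = 1.32),
      G6 = list(dist = "const", value = 0),
      G7 = list(dist = "lnorm", mean = 1.58, sd = 1.70, min = 0, max = 8),
      G8 = list(dist = "lnorm", mean = 1.41, sd = 1.12, min = 0.25, max = 5),
      G9 = list(dist = "norm", mean = 26.6, sd = 2.3, min = 22.8, max = 33)))
}

draw_spec <- function(spec, n) {
  x <- switch(spec$dist,
    const = rep(spec$value, n),
    norm = stats::rnorm(n, spec$mean, spec$sd),
    lnorm = rlnorm_ms(n, spec$mean, spec$sd),
    shiftgamma = {
      shape <- (spec$mean / spec$sd)^2
      spec$shift + stats::rgamma(n, shape = shape,
                                 rate = shape / spec$mean)
    },
    stop("unknown distribution ", spec$dist))
  pmin(spec$max %||% Inf, pmax(spec$min %||% -Inf, x))
}

# lognormal parameterised by its arithmetic mean and SD
rlnorm_ms <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Day-level draws around the subject means. Daily activity volumes vary
# strongly between consecutive days: besides lognormal/Poisson/normal
# wiggle, each day can be an atypical "spell" day with the activity
# features jointly shifted toward the opposite group — a frail person has
# occasional high-activity days (visits, outings) and a robust person
# occasional low-activity ones. Atypical days move steps, periodicity,
# stairs and energy expenditure together, with multipliers chosen so the
# subject mean stays at its calibrated value. Majority votes over 5-day
# blocks are immune to a minority of such days while 5-day feature
# averages are not, which is what separates the two longitudinal designs.
draw_subject_days <- function(subj, n) {
  frail <- subj$label == "frail"
  # atypical-day rates calibrated to the daily error rates the cohort
  # analyses report (frail sensitivity ~93%, robust specificity ~94%)
  p_spike <- if (frail) 0.06 else 0.04
  spike <- stats::runif(n) < p_spike
  k <- sum(spike)
  # canonical day clouds the atypical days are drawn from
  cloud <- if (frail)
    list(G3 = c(3800, 1100), G4 = c(2.5, 1.0), G8 = 1.2,
         G5 = c(1.32, 0.08), G9 = c(25.5, 1.5))
  else
    list(G3 = c(900, 350), G4 = c(0.25, 0.15), G8 = 0.02,
         G5 = c(1.55, 0.15), G9 = c(20.5, 1.5))
  # scale ordinary days so the subject mean stays near its calibrated
  # value (clamped for subjects far below the spike level)
  base_of <- function(m, spike_mean)
    max(0.15 * m, (m - p_spike * spike_mean) / (1 - p_spike))
  # periodicity: the day's count of periodic 30-s windows is Poisson with
  # lognormal day-to-day mixing; a day with no periodic window has G4 = 0
  # and a missing gait period (G5), the common case for frail subjects
  t_mean <- base_of(subj$G4, cloud$G4[1]) * 28.8   # G4 percent -> windows/day
  t_day <- stats::rpois(n, t_mean * rlnorm_ms(n, 1, 0.4))
  g4 <- t_day / 28.8
  # the day's measured gait period averages the peak spacings of its t_day
  # periodic windows, so its noise shrinks with the number of windows
  g5_sd <- pmin(0.25, 0.25 / sqrt(pmax(t_day, 1)))
  g5 <- ifelse(t_day > 0, pmax(0.5, stats::rnorm(n, subj$G5, g5_sd)), NA_real_)
  out <- data.frame(
    G1 = pmin(1, pmax(0, stats::rnorm(n, subj$G1, 0.03))),
    G2 = pmin(100, pmax(0, stats::rnorm(n, subj$G2, 5))),
    G3 = rlnorm_ms(n, 1, 0.3) * base_of(subj$G3, cloud$G3[1]),
    G4 = g4,
    G5 = g5,
    G6 = rep(subj$G6, n),
    G7 = stats::rpois(n, subj$G7),
    G8 = stats::rpois(n, subj$G8),
    G9 = pmax(5, stats::rnorm(n, subj$G9, 1.2)))
  if (k) {
    out$G3[spike] <- pmax(0, stats::rnorm(k, cloud$G3[1], cloud$G3[2]))
    t_spk <- stats::rpois(k, cloud$G4[1] * 28.8)
    out$G4[spike] <- t_spk / 28.8
    out$G5[spike] <- ifelse(t_spk > 0,
                            pmax(0.5, stats::rnorm(k, cloud$G5[1], cloud$G5[2])),
                            NA_real_)
    out$G8[spike] <- stats::rpois(k, cloud$G8)
    out$G9[spike] <- pmax(5, stats::rnorm(k, cloud$G9[1], cloud$G9[2]))
  }
  out
}

#' Generate a synthetic frail/robust cohort
#'
#' Two modes:
#' \describe{
#'   \item{`mode = "features"` (default)}{draws per-subject true feature
#'     means from [cohort_calibration()] and per-day values around them; no
#'     raw signals are synthesised. This is the desk-scale stand-in for the
#'     monitored cohort (18 subjects, about 31.6 +/- 16.5 monitored days
#'     each, about 570 subject-days in total) used by the selection and
#'     classification analyses.}
#'   \item{`mode = "signals"`}{synthesises full signal-level
#'     [day_recording()]s via [generate_day()] with per-subject jitter of
#'     the profile parameters — expensive, intended for small `n`.}
#' }
#'
#' @param n_frail,n_robust Subjects per group (default 9 + 9).
#' @param days_per_subject Days per subject; `NULL` (default) draws
#'   `round(rnorm(31.6, 16.5))` clipped to `[5, 60]`, a single number
#'   fixes it.
#' @param frail,robust [subject_profile()]s used in `"signals"` mode.
#' @param seed Integer seed.
#' @param mode `"features"` or `"signals"`.
#' @param out_dir Optional directory: writes `truth.csv` (feature CSV) and,
#'   in `"signals"` mode, the per-day CSV file pairs and `episodes.json`.
#' @return A list with `features` (daily true-feature data frame in the
#'   feature-CSV layout), `subjects` (per-subject means and labels), and in
#'   `"signals"` mode `recordings` (list of [day_recording()]) and
#'   `episodes`.
#' @export
generate_cohort <- function(n_frail = 9, n_robust = 9,
                            days_per_subject = NULL,
                            frail = frail_profile(), robust = robust_profile(),
                            seed = 1, mode = c("features", "signals"),
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (n_frail < 1 || n_robust < 1) stop("parameter error: counts must be >= 1")
  set.seed(as.integer(seed))
  labels <- c(rep("frail", n_frail), rep("robust", n_robust))
  ids <- sprintf("S%02d", seq_along(labels))
  ndays <- if (is.null(days_per_subject))
    pmin(60, pmax(5, round(stats::rnorm(length(ids), 31.6, 16.5))))
  else rep(days_per_subject, length(ids))

  if (mode == "features") {
    cal <- cohort_calibration()
    gcols <- paste0("G", 1:9)
    subj <- data.frame(subject = ids, label = labels, days = ndays,
                       stringsAsFactors = FALSE)
    for (g in gcols)
      subj[[g]] <- ifelse(labels == "frail",
                          draw_spec(cal$frail[[g]], length(ids)),
                          draw_spec(cal$robust[[g]], length(ids)))
    rows <- lapply(seq_along(ids), function(i) {
      df <- feature_row(ids[i],
                        as.Date("2020-06-01") + seq_len(ndays[i]) - 1,
                        label = labels[i])
      df[gcols] <- draw_subject_days(subj[i, ], ndays[i])
      df
    })
    features <- do.call(rbind, rows)
    out <- list(features = features, subjects = subj)
  } else {
    recordings <- list(); feats <- list(); eps <- list()
    day_seeds <- sample.int(2^31 - 2, sum(ndays))
    k <- 0L
    for (i in seq_along(ids)) {
      prof <- jitter_profile(if (labels[i] == "frail") frail else robust)
      for (d in seq_len(ndays[i])) {
        k <- k + 1L
        g <- generate_day(prof, day_seeds[k], subject_id = ids[i],
                          date = as.Date("2020-06-01") + d - 1)
        recordings[[k]] <- g$recording
        feats[[k]] <- g$truth$features
        ep <- g$truth$episodes
        if (nrow(ep)) {
          ep$subject <- ids[i]; ep$day <- d
          eps[[k]] <- ep
        }
        if (!is.null(out_dir)) {
          paths <- day_paths(out_dir, ids[i], g$recording$date)
          write_day(g$recording, paths["acc"], paths["baro"])
        }
      }
    }
    features <- do.call(rbind, feats)
    out <- list(features = features,
                subjects = data.frame(subject = ids, label = labels,
                                      days = ndays, stringsAsFactors = FALSE),
                recordings = recordings,
                episodes = if (length(eps)) do.call(rbind, eps) else NULL)
    if (!is.null(out_dir) && !is.null(out$episodes))
      jsonlite::write_json(out$episodes, file.path(out_dir, "episodes.json"),
                           dataframe = "rows", auto_unbox = TRUE, na = "null")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(out$features, file.path(out_dir, "truth.csv"))
  }
  out
}

# between-subject variability of the signal-level profiles
jitter_profile <- function(p) {
  ln <- function(x, cv) x * exp(stats::rnorm(1, 0, cv) - cv^2 / 2)
  p$steps_per_day <- ln(p$steps_per_day, 0.25)
  p$periodic_windows_per_day <- ln(p$periodic_windows_per_day, 0.25)
  p$activity_rate <- min(0.6, max(0.03, p$activity_rate + stats::rnorm(1, 0, 0.03)))
  p$stairs_per_day <- ln(p$stairs_per_day, 0.3)
  p$lifts_per_day <- ln(p$lifts_per_day, 0.3)
  p$agitations_per_night <- ln(p$agitations_per_night, 0.3)
  p$cadence_hz <- min(3, max(0.5, p$cadence_hz * (1 + stats::rnorm(1, 0, 0.05))))
  p
}
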