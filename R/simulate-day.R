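#' Generate one synthetic subject-day with ground truth
#'
#' Synthesises 24 h of 50 Hz tri-axial acceleration and 5 Hz barometric
#' pressure/temperature for one subject profile, together with the exact
#' ground truth (daily features and an episode log) implied by the
#' construction. The phenomenology is:
#' \itemize{
#'   \item gravity sits on the vertical axis `ax` when upright (daytime)
#'     and on the frontal axis `az` when lying (22:00-08:00);
#'   \item continuous gait occupies whole 30-s windows as a tapered
#'     fundamental-plus-harmonic oscillation at the profile cadence, one
#'     dominant magnitude peak per step;
#'   \item short walking bursts (1.4-1.8 gait cycles each, two or three per
#'     window over a fidget-noise floor) supply the remaining daily steps
#'     without making a window periodic;
#'   \item other active windows are sedentary fidgeting in a tilted
#'     (non-upright) posture, so they contribute to the activity rate but
#'     never to the step count;
#'   \item nights are still apart from Poisson-placed agitation bursts;
#'   \item lifts are still-wearer pressure ramps and stair episodes are
#'     gait windows with a concurrent moderate ramp, both integer-second
#'     aligned; single-sample pressure spikes are injected away from ramps;
#'   \item additive sensor noise: 0.01 g on each axis, 0.03 mbar on
#'     pressure.
#' }
#'
#' @param profile A [subject_profile()].
#' @param seed Integer seed; the same seed reproduces the day exactly.
#' @param subject_id,date Metadata for the emitted [day_recording()].
#' @return A list with `recording` (a [day_recording()]) and `truth`
#'   (list: `features` one-row feature data frame, `episodes` data frame,
#'   `windows` per-window truth labels).
#' @export
generate_day <- function(profile, seed, subject_id = "S1",
                         date = as.Date("2020-06-01")) {
  stopifnot(inherits(profile, "subject_profile"))
  set.seed(as.integer(seed))
  p <- profile
  fs <- 50L; K <- 2880L; wlen <- 1500L
  n <- K * wlen
  win_start_s <- (seq_len(K) - 1L) * 30
  day_win <- which(win_start_s >= 28800 & win_start_s < 79200)
  f_base <- p$cadence_hz

  # --- daily volumes (day-to-day lognormal jitter, mean-preserving) ---
  mult <- exp(stats::rnorm(1, 0, p$day_cv) - p$day_cv^2 / 2)
  mult_a <- exp(stats::rnorm(1, 0, p$day_cv / 2) - (p$day_cv / 2)^2 / 2)
  steps_target <- round(p$steps_per_day * mult)
  n_per <- min(length(day_win) - 50L, round(p$periodic_windows_per_day * mult))
  n_stair <- stats::rpois(1, p$stairs_per_day)
  n_lift <- stats::rpois(1, p$lifts_per_day)

  avail <- sample(day_win)
  take <- function(k) {
    k <- max(0L, min(k, length(avail)))
    if (k == 0L) return(integer(0))
    out <- avail[seq_len(k)]
    avail <<- avail[-seq_len(k)]
    out
  }
  per_win <- take(n_per)
  stair_win <- take(n_stair); n_stair <- length(stair_win)
  lift_win <- take(n_lift); n_lift <- length(lift_win)
  jump_win <- if (!is.null(p$jumps) && p$jumps$count > 0) take(1L) else integer(0)

  mov <- numeric(n)                      # movement along the gravity axis
  extra_ax <- numeric(n); extra_ay <- numeric(n)
  sub_per_burst <- if (f_base < 0.7) 2L else 3L

  # --- continuous gait windows (periodic + stairs) ---
  gait_win <- c(per_win, stair_win)
  gait_steps <- 0L
  gait_period <- numeric(length(gait_win))
  for (k in seq_along(gait_win)) {
    w <- gait_win[k]
    f_b <- f_base * (1 + stats::rnorm(1, 0, 0.03))
    idx <- (w - 1L) * wlen + seq_len(wlen)
    tt <- (seq_len(wlen) - 1L) / fs
    wave <- gait_wave(tt, f_b, p$step_amplitude_g, stats::runif(1, 0, 2 * pi)) *
      taper(wlen, fs, ramp_s = 1)
    mov[idx] <- mov[idx] + wave
    gait_steps <- gait_steps + count_clean_peaks(wave, 0.05)
    gait_period[k] <- 1 / f_b
  }

  # --- short walking bursts over a fidget floor ---
  remaining <- max(0L, steps_target - gait_steps)
  est_per_burst <- sub_per_burst * 2
  n_burst <- min(length(avail) - 20L, ceiling(remaining / est_per_burst))
  n_burst <- max(0L, n_burst)
  burst_win <- take(n_burst)
  burst_steps <- 0L
  slot_s <- 30 / sub_per_burst
  for (w in burst_win) {
    idx <- (w - 1L) * wlen + seq_len(wlen)
    seg <- stats::rnorm(wlen)
    seg <- (seg - mean(seg)) / stats::sd(seg) * 0.03
    for (j in seq_len(sub_per_burst)) {
      f_b <- f_base * (1 + stats::rnorm(1, 0, 0.03))
      # 1.5 gait cycles starting and ending on a zero crossing, under an
      # arched envelope with a 0.65 floor: exactly two magnitude peaks per
      # sub-burst, all far above the detection threshold, and too few
      # autocorrelation repeats to make the window periodic
      dur <- 1.5 / f_b
      off <- (j - 1) * slot_s + stats::runif(1, 0.5, slot_s - dur - 0.5)
      m <- round(dur * fs)
      tt <- (seq_len(m) - 1L) / fs
      env <- 0.65 + 0.35 * sin(pi * tt / dur)
      wave <- gait_wave(tt, f_b, p$burst_amplitude_g, 0) * env
      i0 <- round(off * fs)
      seg[i0 + seq_len(m)] <- seg[i0 + seq_len(m)] + wave
      burst_steps <- burst_steps + count_clean_peaks(wave, 0.05)
    }
    mov[idx] <- mov[idx] + seg
  }

  # --- nocturnal agitation (night-clock window grid) ---
  nc_order <- c(2641:2880, 1:960)        # 22:00-24:00 then 00:00-08:00
  agit <- place_agitations(stats::rpois(1, p$agitations_per_night),
                           n_slots = length(nc_order))
  agit_win <- integer(0)
  for (r in seq_len(nrow(agit))) {
    wins <- nc_order[agit$pos[r] + seq_len(agit$len[r]) - 1L]
    agit_win <- c(agit_win, wins)
    for (w in wins) {
      idx <- (w - 1L) * wlen + seq_len(wlen)
      mov[idx] <- mov[idx] + stats::rnorm(wlen, 0, 0.1)
      extra_ax[idx] <- stats::rnorm(wlen, 0, 0.1)
      extra_ay[idx] <- stats::rnorm(wlen, 0, 0.1)
    }
  }

  # --- sedentary fidget (tilted) windows to reach the activity target ---
  n_active_core <- n_per + n_stair + n_burst + length(agit_win) +
    length(jump_win)
  n_filler <- max(0L, round(p$activity_rate * mult_a * K) - n_active_core)
  filler_win <- take(n_filler); n_filler <- length(filler_win)
  tilt <- numeric(n)                     # 0 upright, 1 tilted
  for (w in filler_win) {
    idx <- (w - 1L) * wlen + seq_len(wlen)
    seg <- stats::rnorm(wlen)
    seg <- (seg - mean(seg)) / stats::sd(seg) * stats::runif(1, 0.035, 0.08)
    mov[idx] <- mov[idx] + seg
    tilt[idx] <- tilt_profile(wlen, fs, ramp_s = 1.5)
  }

  # --- weightless (jump) intervals ---
  g6_truth <- 0
  jump_ep <- NULL
  if (length(jump_win)) {
    base_s <- (jump_win - 1L) * 30
    len_smp <- max(2L, round(p$jumps$len_s * fs))
    pos <- (jump_win - 1L) * wlen + 1L + fs
    for (j in seq_len(p$jumps$count)) {
      i0 <- pos
      pos <- pos + len_smp + sample(25:75, 1)   # irregular spacing, stays aperiodic
      mov[i0:(i0 + len_smp - 1L)] <- -0.9
      g6_truth <- g6_truth + len_smp / fs
      jump_ep <- rbind(jump_ep,
                       data.frame(kind = "weightless",
                                  start_s = base_s + (i0 - (jump_win - 1L) * wlen - 1L) / fs,
                                  end_s = NA, value = len_smp / fs))
    }
    jump_ep$end_s <- jump_ep$start_s + jump_ep$value
  }

  # --- assemble axes: gravity direction x (1 + movement) + sensor noise ---
  t_acc <- (seq_len(n) - 1L) / fs
  night <- t_acc < 28800 | t_acc >= 79200
  theta <- tilt * 0.99                   # tilt angle in rad; cos(0.99) = 0.55
  gx <- ifelse(night, 0, cos(theta))
  gz <- ifelse(night, 1, sin(theta))
  amp <- 1 + mov
  ax <- gx * amp + extra_ax + stats::rnorm(n, 0, 0.01)
  ay <- extra_ay + stats::rnorm(n, 0, 0.01)
  az <- gz * amp + stats::rnorm(n, 0, 0.01)
  accel <- accel_series(t_acc, ax, ay, az, fs_nominal = fs)

  # --- barometric channel: ramps for lifts/stairs, drift, spikes ---
  ev <- build_altitude_events(stair_win, lift_win, win_start_s)
  tb <- (seq_len(86400L * 5L) - 1L) / 5
  H <- rep(5, length(tb))
  for (r in seq_len(nrow(ev)))
    H <- H + ev$dir[r] * ev$slope[r] *
      pmin(pmax(tb - ev$start_s[r], 0), ev$dur[r])
  pr <- 1013.25 * (1 - 0.0065 * H / 293.15)^(1 / 0.19) +
    0.3 * sin(2 * pi * tb / 86400 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(length(tb), 0, 0.03)
  n_spk <- stats::rpois(1, p$pressure_spikes_per_day)
  if (n_spk > 0 && nrow(ev) >= 0) {
    bad <- rep(FALSE, length(tb))
    for (r in seq_len(nrow(ev)))
      bad <- bad | (tb >= ev$start_s[r] - 10 & tb <= ev$start_s[r] + ev$dur[r] + 10)
    cand <- which(!bad)
    spikes <- sample(cand, min(n_spk, length(cand)))
    pr[spikes] <- pr[spikes] + stats::runif(length(spikes), 1, 4)
  }
  baro <- baro_series(tb, pr, rep(293.15, length(tb)) +
                        stats::rnorm(length(tb), 0, 0.02), fs_nominal = 5)

  rec <- day_recording(subject_id, date, accel, baro, weight_kg = p$weight_kg)

  # --- ground truth ---
  g2 <- truth_sleep_calmness(agit)
  n_active <- n_active_core + n_filler
  n_periodic <- n_per + n_stair
  n_light <- n_burst + n_filler + length(agit_win)
  mets <- (K - n_active) * 1 + n_light * 1.8 + n_periodic * 3.3 +
    length(jump_win) * 7
  truth_feats <- feature_row(subject_id, date,
    G1 = n_active / K,
    G2 = g2,
    G3 = gait_steps + burst_steps,
    G4 = 100 * 30 * n_periodic / 86400,
    G5 = if (n_periodic > 0) mean(gait_period) else NA_real_,
    G6 = g6_truth,
    G7 = n_lift, G8 = n_stair,
    G9 = mets * (30 / 3600),
    label = p$label)
  episodes <- rbind(
    if (nrow(ev)) data.frame(kind = ev$kind,
                             start_s = ev$start_s,
                             end_s = ev$start_s + ev$dur,
                             value = ev$dir * ev$slope * ev$dur),
    if (length(gait_win)) data.frame(kind = "periodic_bout",
                                     start_s = win_start_s[gait_win],
                                     end_s = win_start_s[gait_win] + 30,
                                     value = gait_period),
    if (length(agit_win)) data.frame(kind = "agitation",
                                     start_s = win_start_s[agit_win],
                                     end_s = win_start_s[agit_win] + 30,
                                     value = NA_real_),
    jump_ep)
  if (is.null(episodes)) episodes <- empty_episodes()
  list(recording = rec,
       truth = list(features = truth_feats,
                    episodes = episodes,
                    windows = list(periodic = sort(c(per_win, stair_win)),
                                   burst = sort(burst_win),
                                   filler = sort(filler_win),
                                   agitation = sort(agit_win),
                                   lift = sort(lift_win))))
}

# fundamental + 0.25 x first-harmonic gait oscillation: one local maximum
# per period, a property that survives the 0.5-5 Hz band-pass of the step
# detector even when a slow cadence sits at the band edge (a heavier
# harmonic would gain a second in-band maximum per cycle there)
gait_wave <- function(tt, f, A, phase) {
  A * (sin(2 * pi * f * tt + phase) + 0.25 * sin(4 * pi * f * tt + 2 * phase))
}

# raised-cosine edge taper
taper <- function(m, fs, ramp_s) {
  r <- min(round(ramp_s * fs), floor(m / 2))
  w <- rep(1, m)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    w[seq_len(r)] <- ramp
    w[m + 1L - seq_len(r)] <- ramp
  }
  w
}

# smooth 0 -> 1 -> 0 tilt profile within one window
tilt_profile <- function(m, fs, ramp_s) {
  r <- round(ramp_s * fs)
  w <- rep(1, m)
  ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  w[seq_len(r)] <- ramp
  w[m + 1L - seq_len(r)] <- ramp
  w
}

count_clean_peaks <- function(x, height) {
  n <- length(x)
  if (n < 3L) return(0L)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
        x[2:(n - 1)] > height)
}

# non-overlapping agitation placements on the 1200-window night clock,
# >= 12 windows (6 min) apart so sleep cycles between them stay > 5 min
place_agitations <- function(n_agit, n_slots, min_gap = 12L) {
  out <- data.frame(pos = integer(0), len = integer(0))
  guard <- 0L
  while (nrow(out) < n_agit && guard < 200L) {
    guard <- guard + 1L
    len <- sample(1:3, 1)
    pos <- sample(4:(n_slots - 3L - len), 1)
    if (!nrow(out) ||
        all(abs(out$pos - pos) >= (min_gap + len + out$len)))
      out <- rbind(out, data.frame(pos = pos, len = len))
  }
  out[order(out$pos), , drop = FALSE]
}

# integer-second aligned pressure ramps; lift slopes sit in the fast band
# with margins against the ~0.1 m one-second barometric noise floor, stair
# slopes in the upper stair band for the same reason
build_altitude_events <- function(stair_win, lift_win, win_start_s) {
  ev <- data.frame(kind = character(0), start_s = numeric(0),
                   dur = numeric(0), slope = numeric(0), dir = numeric(0))
  cur <- 0
  mk <- function(kind, w, dur, slope) {
    start <- win_start_s[w] + sample(2:(30 - dur - 2), 1)
    dir <- sample(c(-1, 1), 1)
    if (cur + dir * slope * dur > 40 || cur + dir * slope * dur < -30)
      dir <- -dir
    cur <<- cur + dir * slope * dur
    data.frame(kind = kind, start_s = start, dur = dur, slope = slope,
               dir = dir)
  }
  for (w in stair_win)
    ev <- rbind(ev, mk("stairs", w, sample(8:14, 1), stats::runif(1, 0.46, 0.54)))
  for (w in lift_win)
    ev <- rbind(ev, mk("lift", w, sample(16:20, 1), stats::runif(1, 0.85, 0.88)))
  if (nrow(ev)) ev[order(ev$start_s), , drop = FALSE] else ev
}

# ground-truth sleep calmness from the agitation layout: cycles are the
# still spans (> 5 min) between interruptions on the 10-h night clock
truth_sleep_calmness <- function(agit) {
  night_len <- 36000
  if (!nrow(agit)) return(100)
  int_start <- (agit$pos - 1) * 30
  int_end <- int_start + agit$len * 30
  bounds <- c(0, as.vector(rbind(int_start, int_end)), night_len)
  seg_start <- bounds[seq(1, length(bounds), by = 2)]
  seg_end <- bounds[seq(2, length(bounds), by = 2)]
  dur <- seg_end - seg_start
  cyc <- dur > 300
  if (!any(cyc)) return(NA_real_)
  spt <- sum(dur[cyc])
  span <- max(seg_end[cyc]) - min(seg_start[cyc])
  100 * spt / span
}
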