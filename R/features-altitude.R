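#' Lift and stair counts from the change in altitude (G7, G8)
#'
#' Scans the 1-s altitude series for maximal runs where altitude rises or
#' falls continuously for at least `min_run_s` seconds (single-second
#' plateaus with `|dH| < plateau_m` are tolerated inside a run). The slope
#' of a run is the straight-line `delta H / duration`. A run is a *lift*
#' when `|slope|` lies in `lift_band` while the wearer is concurrently
#' inactive or only slightly moving, and a *stair* episode when `|slope|`
#' lies in `stair_band` while the wearer is active. The shared 0.6 m/s
#' boundary is resolved by the activity gate, ties defaulting to stairs
#' when active. G7 counts lifts, G8 stair episodes.
#'
#' @param alt An `altitude_series` from [altitude()].
#' @param windows Window data frame from [activity_windows()], used for the
#'   concurrent activity state (each second inherits the rms of its 30-s
#'   window: inactive <= 0.03 g, slightly moving (0.03, 0.06], active
#'   > 0.03 g).
#' @param min_run_s Minimum monotone-run duration (default 6 s).
#' @param lift_band,stair_band Absolute slope bands in m/s (defaults
#'   `c(0.6, 0.9)` and `c(0.25, 0.6)`).
#' @param plateau_m Plateau tolerance inside a run (default 0.1 m).
#' @param slight_rms_g Upper rms bound of "slightly moving" (default 0.06).
#' @param active_rms_g Activity threshold (default 0.03).
#' @return A list with `G7`, `G8` and `episodes` (data frame: `kind`,
#'   `start_s`, `end_s`, `dH_m`, `slope_m_per_s`).
#' @export
change_in_altitude <- function(alt, windows, min_run_s = 6,
                               lift_band = c(0.6, 0.9),
                               stair_band = c(0.25, 0.6),
                               plateau_m = 0.1,
                               slight_rms_g = 0.06, active_rms_g = 0.03) {
  stopifnot(inherits(alt, "altitude_series"))
  h <- alt$h
  if (all(is.na(h)))
    return(list(G7 = NA_integer_, G8 = NA_integer_, episodes = empty_cia()))
  runs <- monotone_runs(alt$t, h, min_run_s, plateau_m)
  if (nrow(runs) == 0L)
    return(list(G7 = 0L, G8 = 0L, episodes = empty_cia()))
  # concurrent rms per run from the covering activity windows
  rms_of <- function(t0, t1) {
    i <- which(windows$start_s < t1 & (windows$start_s + windows$length_s) > t0)
    if (!length(i)) return(0)
    max(windows$rms[i])
  }
  kind <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s <- abs(runs$slope[i])
    rms <- rms_of(runs$start_s[i], runs$end_s[i])
    active <- rms > active_rms_g
    calm <- rms <= slight_rms_g            # inactive or slightly moving
    if (active && s >= stair_band[1] && s <= stair_band[2]) kind[i] <- "stairs"
    else if (calm && s >= lift_band[1] && s <= lift_band[2]) kind[i] <- "lift"
    else kind[i] <- "none"
  }
  keep <- kind != "none"
  episodes <- data.frame(kind = kind[keep],
                         start_s = runs$start_s[keep], end_s = runs$end_s[keep],
                         dH_m = runs$dH[keep], slope_m_per_s = runs$slope[keep])
  list(G7 = sum(kind == "lift"), G8 = sum(kind == "stairs"), episodes = episodes)
}

empty_cia <- function() {
  data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0),
             dH_m = numeric(0), slope_m_per_s = numeric(0))
}

# maximal monotone runs in a 1-s altitude series, tolerating single-second
# plateaus (|dH| < plateau_m); slope is total dH over the run duration
monotone_runs <- function(t, h, min_run_s, plateau_m) {
  ok <- !is.na(h)
  out <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= 2L)) {
    seg <- starts[k]:ends[k]
    out[[length(out) + 1L]] <- monotone_runs_segment(t[seg], h[seg],
                                                    min_run_s, plateau_m)
  }
  if (!length(out)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                      dH = numeric(0), slope = numeric(0)))
  do.call(rbind, out)
}

monotone_runs_segment <- function(t, h, min_run_s, plateau_m) {
  dh <- diff(h)
  dir <- ifelse(abs(dh) < plateau_m, 0L, ifelse(dh > 0, 1L, -1L))
  res <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    dH = numeric(0), slope = numeric(0))
  n <- length(dir)
  i <- 1L
  while (i <= n) {
    if (dir[i] == 0L) { i <- i + 1L; next }
    d <- dir[i]
    j <- i
    plateau_run <- 0L
    while (j < n) {
      nxt <- dir[j + 1L]
      if (nxt == d) { plateau_run <- 0L; j <- j + 1L }
      else if (nxt == 0L && plateau_run == 0L) { plateau_run <- 1L; j <- j + 1L }
      else break
    }
    while (j >= i && dir[j] == 0L) j <- j - 1L   # trim trailing plateau
    dur <- t[j + 1L] - t[i]
    if (dur >= min_run_s) {
      res <- rbind(res, data.frame(start_s = t[i], end_s = t[j + 1L],
                                   dH = h[j + 1L] - h[i],
                                   slope = (h[j + 1L] - h[i]) / dur))
    }
    i <- j + 1L
  }
  res
}
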