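#' Tracker configuration
#'
#' Settings for converting inhale/exhale keypress onsets into a continuous
#' breathing phase and tempo. Phase snaps to 0 degrees at an inhale onset and
#' to `exhale_phase` at an exhale onset; between onsets it free-runs linearly
#' at the current tempo and wraps at 360.
#'
#' @param exhale_phase Phase (degrees) assigned at an exhale onset. Default 240,
#'   the system's literal convention. Note a strict 1:2 inhale:exhale split
#'   would place the exhale onset at 120 degrees; the constant is configurable
#'   precisely because the two conventions differ (see the methods vignette).
#' @param ioi_window Number of most recent inter-onset intervals used for the
#'   tempo median. Default 5.
#' @param default_period Full-cycle period (seconds) assumed before enough
#'   onsets exist. Default 5 s, i.e. 12 breaths/min.
#' @param debounce Minimum seconds between accepted onsets; closer events are
#'   rejected as key double-fires. Default 0.2 s.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(exhale_phase = 240, ioi_window = 5,
                           default_period = 5, debounce = 0.2) {
  stopifnot(exhale_phase > 0, exhale_phase < 360, ioi_window >= 1,
            default_period > 0, debounce >= 0)
  structure(
    list(exhale_phase = exhale_phase, ioi_window = as.integer(ioi_window),
         default_period = default_period, debounce = debounce),
    class = "tracker_config"
  )
}

#' Create a fresh breath tracker
#'
#' The tracker state holds the current period, the phase at the last accepted
#' onset, the recent inter-onset-interval history (mixed half-cycle intervals)
#' and recent inhale-to-inhale full-cycle intervals.
#'
#' @param cfg A [tracker_config()].
#' @return A list of class `breath_tracker`. Its `status` field records the
#'   outcome of the last [ingest_onset()] call: `"init"`, `"accepted"`,
#'   `"rejected_debounce"` or `"rejected_nonmonotone"`.
#' @export
breath_tracker <- function(cfg = tracker_config()) {
  structure(
    list(
      period = cfg$default_period,
      phase_at_last_onset = 0,
      last_time = NA_real_,
      last_kind = NA_character_,
      last_inhale_time = NA_real_,
      ioi = numeric(0),       # mixed half-cycle intervals, most recent last
      full_ioi = numeric(0),  # inhale -> inhale full-cycle intervals
      n_accepted = 0L,
      status = "init"
    ),
    class = "breath_tracker"
  )
}

#' Ingest one onset event
#'
#' Accepts or rejects a keypress onset. On acceptance the phase snaps to 0
#' (inhale) or `cfg$exhale_phase` (exhale), the interval since the previous
#' accepted onset is appended to the history, and the period estimate is
#' refreshed. Events within `cfg$debounce` of the previous accepted event are
#' rejected without state change (`status = "rejected_debounce"`); events not
#' after the previous accepted event are rejected as non-monotone
#' (`status = "rejected_nonmonotone"`).
#'
#' @param state A `breath_tracker`.
#' @param time Event time, seconds from trial start.
#' @param kind `"inhale"` or `"exhale"`.
#' @param cfg A [tracker_config()].
#' @return The updated `breath_tracker`; inspect `$status` for the outcome.
#' @export
ingest_onset <- function(state, time, kind = c("inhale", "exhale"),
                         cfg = tracker_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(state, "breath_tracker"), time >= 0)
  if (!is.na(state$last_time)) {
    if (time <= state$last_time) {
      state$status <- "rejected_nonmonotone"
      return(state)
    }
    if (time - state$last_time < cfg$debounce) {
      state$status <- "rejected_debounce"
      return(state)
    }
    ioi <- time - state$last_time
    state$ioi <- tail(c(state$ioi, ioi), cfg$ioi_window)
  }
  if (kind == "inhale") {
    if (!is.na(state$last_inhale_time)) {
      state$full_ioi <- tail(c(state$full_ioi, time - state$last_inhale_time),
                             cfg$ioi_window)
    }
    state$last_inhale_time <- time
    state$phase_at_last_onset <- 0
  } else {
    state$phase_at_last_onset <- cfg$exhale_phase
  }
  state$last_time <- time
  state$last_kind <- kind
  state$n_accepted <- state$n_accepted + 1L
  state$period <- estimate_period(state, cfg)
  state$status <- "accepted"
  state
}

# Median of the most recent mixed half-cycle inter-onset intervals (the
# system's literal tempo statistic); NA when the history is empty.
median_ioi <- function(state, cfg = tracker_config()) {
  h <- tail(state$ioi, cfg$ioi_window)
  if (length(h) == 0) return(NA_real_)
  median(h)
}

#' Estimate the full-cycle breathing period
#'
#' Period is the median of the recent inhale-to-inhale full-cycle intervals
#' when at least one such interval exists; otherwise twice the median of the
#' mixed half-cycle inter-onset intervals; otherwise `cfg$default_period`.
#' Full-cycle intervals are preferred because they are invariant to the
#' inhale:exhale ratio.
#'
#' @inheritParams ingest_onset
#' @return Period in seconds (always positive).
#' @export
estimate_period <- function(state, cfg = tracker_config()) {
  full <- tail(state$full_ioi, cfg$ioi_window)
  if (length(full) > 0) return(median(full))
  half <- median_ioi(state, cfg)
  if (!is.na(half)) return(2 * half)
  cfg$default_period
}

#' Breathing phase at an arbitrary time
#'
#' Linear interpolation from the last accepted onset at the current tempo:
#' `(phase_at_last_onset + 360 * (t - last_time) / period) mod 360`. Before
#' any onset has been accepted the phase free-runs from 0 at t = 0 using the
#' default period.
#'
#' @param state A `breath_tracker`.
#' @param t Query time(s), seconds; must not precede the last accepted onset.
#' @param cfg A [tracker_config()].
#' @return Phase in degrees, in `[0, 360)`; vectorised over `t`.
#' @export
phase_at <- function(state, t, cfg = tracker_config()) {
  t0 <- if (is.na(state$last_time)) 0 else state$last_time
  if (any(t < t0)) {
    abort("`t` precedes the last accepted onset", class = "breathsync_time_error")
  }
  wrap360(state$phase_at_last_onset + 360 * (t - t0) / state$period)
}

#' Track breathing over a whole event log
#'
#' Convenience wrapper: ingests a tibble of onsets and samples phase and
#' period on a regular grid.
#'
#' @param events Tibble with columns `time` (seconds) and `kind`
#'   (`"inhale"`/`"exhale"`), as returned by [read_keypress_log()] or
#'   [closed_loop_session()].
#' @param cfg A [tracker_config()].
#' @param dt Sampling step in seconds (default 0.01).
#' @param duration Total duration; defaults to the last event time.
#' @return Tibble with columns `time`, `phase` (degrees), `period` (seconds).
#' @export
track_breathing <- function(events, cfg = tracker_config(), dt = 0.01,
                            duration = NULL) {
  stopifnot(all(c("time", "kind") %in% names(events)))
  duration <- duration %||% max(events$time)
  grid <- seq(0, duration, by = dt)
  st <- breath_tracker(cfg)
  phase <- numeric(length(grid))
  period <- numeric(length(grid))
  ev_i <- 1L
  n_ev <- nrow(events)
  for (i in seq_along(grid)) {
    t <- grid[i]
    while (ev_i <= n_ev && events$time[ev_i] <= t) {
      st <- ingest_onset(st, events$time[ev_i], events$kind[ev_i], cfg)
      ev_i <- ev_i + 1L
    }
    phase[i] <- phase_at(st, t, cfg)
    period[i] <- st$period
  }
  tibble(time = grid, phase = phase, period = period)
}
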