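#' Virtual breather parameters
#'
#' A simulated participant emitting inhale/exhale onsets. Each onset time is a
#' convex blend of the breather's intrinsic timing and the stimulus's next
#' corresponding phase landmark, plus truncated Gaussian jitter; the
#' inhale:exhale ratio drifts toward the stimulus's ratio once sound plays.
#'
#' @param intrinsic_rate Breaths per minute in the absence of any stimulus.
#'   Default 8 (a calm but above-target resting rate; the biofeedback goal is
#'   ~6 breaths/min).
#' @param intrinsic_ratio Exhale/inhale duration ratio. Default 1.5 (below
#'   the 2.0 target, as untrained breathing typically is).
#' @param jitter_sd SD of the Gaussian onset jitter, seconds, truncated at
#'   +/- 3 SD so intervals stay positive. Default 0.15.
#' @param entrain_gain Weight in `[0, 1]` of the stimulus landmark in the
#'   timing blend; 0 = deaf breather, 1 = fully captured. Default 0.5.
#' @param ratio_gain Per-cycle drift rate of the ratio toward the stimulus
#'   ratio, in `[0, 1]`. Default 0.1.
#' @return A list of class `breather_params`.
#' @export
breather_params <- function(intrinsic_rate = 8, intrinsic_ratio = 1.5,
                            jitter_sd = 0.15, entrain_gain = 0.5,
                            ratio_gain = 0.1) {
  stopifnot(intrinsic_rate > 0, intrinsic_ratio > 0, jitter_sd >= 0,
            entrain_gain >= 0, entrain_gain <= 1,
            ratio_gain >= 0, ratio_gain <= 1)
  structure(
    list(intrinsic_rate = intrinsic_rate, intrinsic_ratio = intrinsic_ratio,
         jitter_sd = jitter_sd, entrain_gain = entrain_gain,
         ratio_gain = ratio_gain),
    class = "breather_params"
  )
}

# Truncated N(0, sd) draw, cut at +/- 3 sd.
trunc_jitter <- function(sd) {
  if (sd == 0) return(0)
  max(min(rnorm(1, 0, sd), 3 * sd), -3 * sd)
}

#' Next onset of the virtual breather
#'
#' Computes the time and kind of the breather's next onset from its state
#' after the current onset. With no stimulus (or `entrain_gain = 0`) timing
#' is purely intrinsic; with a stimulus the time is blended toward the moment
#' the stimulus phase next reaches the landmark angle for that onset kind
#' (0 degrees for an inhale, `landmarks["exhale"]` for an exhale). Consumes
#' RNG for the jitter draw.
#'
#' @param state List with `time` and `kind` of the onset just emitted and the
#'   breather's current `ratio`.
#' @param params A [breather_params()].
#' @param stim Either `NULL` (no audible stimulus) or a list with the
#'   stimulus `phase` (degrees, at `state$time`) and `freq` (Hz).
#' @param landmarks Named angles (degrees) at which the stimulus marks the
#'   inhale and exhale onsets of its cycle; defaults match the renderer's
#'   envelope split.
#' @return List with `time` and `kind` of the next onset.
#' @export
next_onset <- function(state, params, stim = NULL,
                       landmarks = c(inhale = 0, exhale = 120)) {
  next_kind <- if (state$kind == "inhale") "exhale" else "inhale"
  period <- 60 / params$intrinsic_rate
  ratio <- state$ratio
  interval <- if (next_kind == "exhale") {
    period / (1 + ratio)          # inhale duration
  } else {
    period * ratio / (1 + ratio)  # exhale duration
  }
  t_next <- state$time + interval
  if (!is.null(stim) && params$entrain_gain > 0) {
    ang <- landmarks[[next_kind]]
    lead <- wrap360(ang - stim$phase) / 360 / stim$freq
    if (lead < 0.3 * interval) lead <- lead + 1 / stim$freq
    t_land <- state$time + lead
    t_next <- (1 - params$entrain_gain) * t_next + params$entrain_gain * t_land
  }
  t_next <- t_next + trunc_jitter(params$jitter_sd)
  list(time = max(t_next, state$time + 0.25), kind = next_kind)
}

#' Open-loop virtual breathing (events only)
#'
#' Fast path for an uncoupled breather: generates a jittered periodic onset
#' stream at the intrinsic rate and ratio, with no stimulus interaction.
#'
#' @param params A [breather_params()] (its `entrain_gain` is ignored here).
#' @param duration Seconds of breathing to generate.
#' @param seed Integer seed.
#' @param t0 Time of the first inhale (default 1 s).
#' @return Tibble of onset events (`time`, `kind`).
#' @export
simulate_breather_events <- function(params, duration = 480, seed = 1, t0 = 1) {
  with_seed(seed, {
    times <- numeric(0)
    kinds <- character(0)
    st <- list(time = t0, kind = "inhale", ratio = params$intrinsic_ratio)
    times <- st$time; kinds <- st$kind
    repeat {
      nxt <- next_onset(st, params, stim = NULL)
      if (nxt$time >= duration) break
      st <- list(time = nxt$time, kind = nxt$kind, ratio = st$ratio)
      times <- c(times, st$time); kinds <- c(kinds, st$kind)
    }
    tibble(time = times, kind = kinds)
  })
}

#' Run a full closed-loop biofeedback session
#'
#' Integrates the whole system at the control rate: the schedule selects the
#' alignment mode, the tracker converts the virtual breather's keypresses to
#' phase and tempo, the stimulus oscillator is Kuramoto-coupled to the
#' tracked phase (frequency-only in tempo-aligned mode), synchronization is
#' measured as the mean resultant length over a trailing window, and in the
#' delayed mode the gated delay makes the stimulus trail the breather —
#' steering an entrained breather toward slower breathing. Fully
#' deterministic given `seed`.
#'
#' @param params A [breather_params()].
#' @param schedule A [build_schedule()] result.
#' @param tracker_cfg A [tracker_config()].
#' @param coupling_cfg A [coupling_config()].
#' @param stim_cfg A [stimulus_config()] (supplies the landmark split).
#' @param seed Integer seed.
#' @return A `session_log`: list with `events` (onset tibble), `trace`
#'   (control-rate tibble: `time`, `mode`, `breather_phase`, `stim_phase`,
#'   `stim_freq`, `R`, `delay`), `schedule`, `params`, `seed`.
#' @export
closed_loop_session <- function(params = breather_params(),
                                schedule = build_schedule(),
                                tracker_cfg = tracker_config(),
                                coupling_cfg = coupling_config(),
                                stim_cfg = stimulus_config(),
                                seed = 1) {
  dt <- coupling_cfg$dt
  total <- schedule_total(schedule)
  n_steps <- floor(total / dt)
  landmarks <- c(inhale = 0, exhale = stim_cfg$inhale_end_phase)
  stim_ratio <- (360 - stim_cfg$inhale_end_phase) / stim_cfg$inhale_end_phase

  tr_time <- (seq_len(n_steps) - 1) * dt
  tr_mode <- mode_at(schedule, tr_time)
  tr_bphase <- numeric(n_steps); tr_sphase <- numeric(n_steps)
  tr_freq <- numeric(n_steps); tr_R <- numeric(n_steps)
  tr_delay <- numeric(n_steps)

  win_len <- max(1L, floor(coupling_cfg$sync_window / dt))
  bbuf <- numeric(win_len); sbuf <- numeric(win_len)
  buf_n <- 0L; buf_i <- 0L
  r_every <- max(1L, floor(0.5 / dt))   # refresh R at 2 Hz

  with_seed(seed, {
    st <- breath_tracker(tracker_cfg)
    stim <- oscillator(natural_freq = 1 / tracker_cfg$default_period)
    br <- list(time = 1, kind = "inhale", ratio = params$intrinsic_ratio)
    ev_time <- br$time; ev_kind <- br$kind
    pending <- NULL
    R <- 0; delay <- 0

    for (i in seq_len(n_steps)) {
      t <- tr_time[i]
      mode <- tr_mode[i]
      audible <- mode != "silence"

      # emit breather onsets due at or before t
      while (TRUE) {
        if (is.null(pending)) {
          stim_view <- if (audible) {
            list(phase = stim$phase, freq = stim$current_freq)
          } else NULL
          pending <- next_onset(br, params, stim_view, landmarks)
        }
        if (pending$time > t) break
        br <- list(time = pending$time, kind = pending$kind, ratio = br$ratio)
        if (br$kind == "inhale" && audible) {
          br$ratio <- br$ratio + params$ratio_gain * (stim_ratio - br$ratio)
        }
        ev_time <- c(ev_time, br$time); ev_kind <- c(ev_kind, br$kind)
        st <- ingest_onset(st, br$time, br$kind, tracker_cfg)
        pending <- NULL
      }

      bphase <- phase_at(st, t, tracker_cfg)

      # synchronization window + gated delay
      buf_i <- if (buf_i == win_len) 1L else buf_i + 1L
      bbuf[buf_i] <- bphase; sbuf[buf_i] <- stim$phase
      if (buf_n < win_len) buf_n <- buf_n + 1L
      if (audible && i %% r_every == 0L) {
        R <- mean_vector_length(bbuf[seq_len(buf_n)], sbuf[seq_len(buf_n)])
      }
      off <- target_offset(mode, R, coupling_cfg)
      delay <- if (mode == "phase_delayed") off$offset else 0

      if (audible) {
        stim <- kuramoto_step(
          stim, bphase, coupling_cfg,
          target_offset = if (off$coupled) off$offset else 0,
          breather_freq = 1 / st$period,
          phase_coupled = off$coupled
        )
      }

      tr_bphase[i] <- bphase; tr_sphase[i] <- stim$phase
      tr_freq[i] <- stim$current_freq; tr_R[i] <- R; tr_delay[i] <- delay
    }

    keep <- ev_time < total
    structure(
      list(
        events = tibble(time = ev_time[keep], kind = ev_kind[keep]),
        trace = tibble(time = tr_time, mode = tr_mode,
                       breather_phase = tr_bphase, stim_phase = tr_sphase,
                       stim_freq = tr_freq, R = tr_R, delay = tr_delay),
        schedule = schedule, params = params, seed = seed
      ),
      class = "session_log"
    )
  })
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d onsets over %.0f s (seed %d)\n",
              nrow(x$events), schedule_total(x$schedule), x$seed))
  cat(sprintf("  final R = %.3f, final stimulus freq = %.3f Hz\n",
              tail(x$trace$R, 1), tail(x$trace$stim_freq, 1)))
  invisible(x)
}
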