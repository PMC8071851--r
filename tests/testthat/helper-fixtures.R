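# Jitter-free periodic onset stream: full period 60/rate seconds, exhale
# lasting `ratio` times the inhale, first inhale at t0.
make_periodic_events <- function(rate = 10, ratio = 2, duration = 480, t0 = 0) {
  period <- 60 / rate
  inhale_d <- period / (1 + ratio)
  times <- numeric(0)
  kinds <- character(0)
  t <- t0
  while (t < duration) {
    times <- c(times, t, t + inhale_d)
    kinds <- c(kinds, "inhale", "exhale")
    t <- t + period
  }
  keep <- times < duration
  tibble::tibble(time = times[keep], kind = kinds[keep])
}

# Ingest a whole event tibble into a fresh tracker.
ingest_all <- function(events, cfg = tracker_config()) {
  st <- breath_tracker(cfg)
  for (i in seq_len(nrow(events))) {
    st <- ingest_onset(st, events$time[i], events$kind[i], cfg)
  }
  st
}

# Free-running uniform stimulus phase trajectory at `freq` Hz.
uniform_phase_traj <- function(freq = 0.2, duration = 60, dt = 0.01) {
  t <- seq(0, duration - dt, by = dt)
  tibble::tibble(time = t, phase = (360 * freq * t) %% 360)
}
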