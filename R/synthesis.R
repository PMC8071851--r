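#' Stimulus configuration
#'
#' Parameters shared by the three stimulus families. The breathing envelope
#' splits the cycle at `inhale_end_phase` (default 120 degrees, i.e. the 1:2
#' inhale:exhale target: exhale occupies two thirds of a uniformly advancing
#' cycle); this split is deliberately independent of the tracker's exhale
#' snap constant (see the methods vignette).
#'
#' @param sample_rate Audio sample rate, Hz.
#' @param control_rate Control-signal rate, Hz.
#' @param inhale_end_phase Degrees at which the inhale region of the envelope
#'   ends and the exhale region begins.
#' @param amp_trough Envelope level at the onsets (the minima), in `[0, 1)`.
#' @param cutoff_min,cutoff_max Low-pass cutoff range, Hz.
#' @param fade Early-inhale fade-out length, seconds.
#' @param r_min,r_max Spatial radius range of the nature scene.
#' @param radius_expand_on `"inhale"` or `"exhale"`: where in the cycle the
#'   nature scene's circle of sources is widest.
#' @param music_noise_gain Gain of the breath-noise bed under the music.
#' @param arpeggio_pitches MIDI pitches of the descending arpeggio
#'   (default a C-major arpeggio from C6).
#' @param chord_pitches List of three MIDI chords for the ii-V-I progression
#'   (default Dm7, G7, Cmaj7).
#' @return A list of class `stimulus_config`.
#' @export
stimulus_config <- function(sample_rate = 44100, control_rate = 100,
                            inhale_end_phase = 120, amp_trough = 0.05,
                            cutoff_min = 200, cutoff_max = 4000,
                            fade = 0.15, r_min = 0.2, r_max = 1,
                            radius_expand_on = c("inhale", "exhale"),
                            music_noise_gain = 0.4,
                            arpeggio_pitches = c(84, 79, 76, 72),
                            chord_pitches = list(c(62, 65, 69, 72),
                                                 c(55, 59, 62, 65),
                                                 c(48, 52, 55, 59))) {
  radius_expand_on <- match.arg(radius_expand_on)
  stopifnot(inhale_end_phase > 0, inhale_end_phase < 360,
            amp_trough >= 0, amp_trough < 1, cutoff_min > 0,
            cutoff_max > cutoff_min, fade > 0, r_min >= 0, r_max > r_min)
  structure(
    list(sample_rate = sample_rate, control_rate = control_rate,
         inhale_end_phase = inhale_end_phase, amp_trough = amp_trough,
         cutoff_min = cutoff_min, cutoff_max = cutoff_max, fade = fade,
         r_min = r_min, r_max = r_max, radius_expand_on = radius_expand_on,
         music_noise_gain = music_noise_gain,
         arpeggio_pitches = arpeggio_pitches, chord_pitches = chord_pitches),
    class = "stimulus_config"
  )
}

#' Generate pink (1/f) noise
#'
#' Filtered-white pink noise with a -3 dB/octave (-10 dB/decade) power
#' spectral slope, using the Kellett cascade of first-order recursions, each
#' evaluated with `stats::filter`. Deterministic given `seed`; peak-normalised
#' to 0.9.
#'
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @param sample_rate Sample rate in Hz (stored in the buffer).
#' @return A mono [audio_buffer()].
#' @export
generate_pink_noise <- function(n, seed = 1, sample_rate = 44100) {
  stopifnot(n > 0)
  w <- with_seed(seed, rnorm(n))
  a <- c(0.99886, 0.99332, 0.96900, 0.86650, 0.55000, -0.7616)
  g <- c(0.0555179, 0.0750759, 0.1538520, 0.3104856, 0.5329522, -0.0168980)
  pink <- rep(0, n)
  for (k in seq_along(a)) {
    pink <- pink + as.numeric(stats::filter(w * g[k], a[k], method = "recursive"))
  }
  pink <- pink + 0.5362 * w + 0.115926 * c(0, w[-n])
  pink <- pink * (0.9 / max(abs(pink)))
  audio_buffer(pink, sample_rate)
}

#' Breathing envelope from a phase trajectory
#'
#' Maps a stimulus phase trajectory to amplitude, low-pass cutoff and spatial
#' radius control signals. Within each region (inhale: phase below
#' `inhale_end_phase`; exhale: above) the amplitude is a raised cosine with a
#' single peak mid-region and minima exactly at the onsets ("smooth ramps
#' toward the onset"); the cutoff follows the same shape between
#' `cutoff_min` and `cutoff_max`. For a uniformly advancing phase the exhale
#' region lasts `(360 - inhale_end_phase) / inhale_end_phase` times the
#' inhale region — 2.0 with the defaults, the 1:2 target ratio.
#'
#' @param phase_traj Tibble with columns `time` (seconds) and `phase`
#'   (degrees), sampled at the control rate.
#' @param cfg A [stimulus_config()].
#' @return A tibble (`stimulus_control`) with columns `time`, `phase`,
#'   `region`, `amp`, `cutoff`, `radius`.
#' @export
breath_envelope <- function(phase_traj, cfg = stimulus_config()) {
  stopifnot(all(c("time", "phase") %in% names(phase_traj)))
  split <- cfg$inhale_end_phase
  phi <- wrap360(phase_traj$phase)
  inhale <- phi < split
  u <- ifelse(inhale, phi / split, (phi - split) / (360 - split))
  shape <- 0.5 * (1 - cos(2 * pi * u))
  out <- tibble(
    time = phase_traj$time,
    phase = phi,
    region = ifelse(inhale, "inhale", "exhale"),
    amp = cfg$amp_trough + (1 - cfg$amp_trough) * shape,
    cutoff = cfg$cutoff_min + (cfg$cutoff_max - cfg$cutoff_min) * shape,
    radius = nature_radius(phi, cfg)
  )
  structure(out, class = c("stimulus_control", class(out)))
}

# Time-varying one-pole low-pass: y[i] = y[i-1] + a[i] (x[i] - y[i-1]).
# a = 1 (cutoff at or above Nyquist) is an exact passthrough.
onepole_tv <- function(x, a) {
  n <- length(x)
  y <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    prev <- prev + a[i] * (x[i] - prev)
    y[i] <- prev
  }
  y
}

cutoff_to_coef <- function(cutoff, sample_rate) {
  ifelse(cutoff >= sample_rate / 2, 1, 1 - exp(-2 * pi * cutoff / sample_rate))
}

#' Render the breath-like noise stimulus
#'
#' Pink noise low-pass filtered with a time-varying one-pole tracking the
#' envelope's cutoff trajectory, then amplitude modulated and duplicated to
#' stereo. Peak-limited to 0.99.
#'
#' @param control A [breath_envelope()] result.
#' @param noise A mono [audio_buffer()] of pink noise covering the control
#'   duration.
#' @param cfg A [stimulus_config()].
#' @return A stereo [audio_buffer()].
#' @export
render_noise_stimulus <- function(control, noise, cfg = stimulus_config()) {
  sr <- noise$sample_rate
  n <- nrow(noise$samples)
  dur_ctrl <- max(control$time)
  if (abs(n / sr - (dur_ctrl + 1 / cfg$control_rate)) > 0.5) {
    abort("control and noise durations disagree", class = "breathsync_synth_error")
  }
  ts <- (seq_len(n) - 1) / sr
  amp <- approx(control$time, control$amp, xout = ts, rule = 2)$y
  cutoff <- approx(control$time, control$cutoff, xout = ts, rule = 2)$y
  y <- onepole_tv(noise$samples[, 1], cutoff_to_coef(cutoff, sr)) * amp
  normalize_peak(audio_buffer(cbind(y, y), sr))
}

#' Compose one exhale-spanning musical phrase
#'
#' A descending arpeggio followed by a ii-V-I chord progression of a
#' marimba-like sound, notated so that the phrase spans the exhale: total
#' duration `2/3 * period` (exhale twice the inhale). All onsets and
#' durations scale linearly with the period.
#'
#' @param period Full breathing period in seconds.
#' @param cfg A [stimulus_config()].
#' @return A tibble of note events: `onset`, `duration` (seconds), `pitch`
#'   (MIDI number), `velocity` in `[0, 1]`, `role` (`"arpeggio"`/`"chord"`).
#' @export
compose_music_phrase <- function(period, cfg = stimulus_config()) {
  stopifnot(period > 0)
  span <- period * 2 / 3
  arp <- tibble(
    onset = span * seq(0, 0.3, by = 0.1),
    duration = span * 0.1,
    pitch = cfg$arpeggio_pitches,
    velocity = 0.8,
    role = "arpeggio"
  )
  chords <- purrr::imap_dfr(cfg$chord_pitches, function(p, i) {
    tibble(onset = span * (0.4 + 0.2 * (i - 1)), duration = span * 0.2,
           pitch = p, velocity = 0.6, role = "chord")
  })
  bind_rows(arp, chords)
}

midi_to_hz <- function(m) 440 * 2^((m - 69) / 12)

# Additive marimba-ish tone bank: fundamental + detuned 4th partial,
# exponentially decaying.
render_notes <- function(notes, duration, sample_rate) {
  n <- ceiling(duration * sample_rate)
  out <- numeric(n)
  for (i in seq_len(nrow(notes))) {
    f <- midi_to_hz(notes$pitch[i])
    len <- min(notes$duration[i] * 3, duration - notes$onset[i])
    if (len <= 0) next
    m <- floor(len * sample_rate)
    t <- (seq_len(m) - 1) / sample_rate
    tau <- notes$duration[i]
    tone <- notes$velocity[i] *
      (sin(2 * pi * f * t) * exp(-t / tau) +
         0.4 * sin(2 * pi * 3.9 * f * t) * exp(-t / (tau / 3)))
    i0 <- floor(notes$onset[i] * sample_rate) + 1
    idx <- i0:min(i0 + m - 1, n)
    out[idx] <- out[idx] + tone[seq_along(idx)]
  }
  out
}

#' Fade a phrase out at an early inhale
#'
#' Linear gain ramp from 1 to 0 over `cfg$fade` seconds starting at
#' `inhale_time`; samples after the ramp are silenced. Applied to the phrase
#' stem only, emulating the quick fade-out when an inhale interrupts the
#' harmonic resolution.
#'
#' @param audio An [audio_buffer()] holding the phrase stem.
#' @param inhale_time Seconds from buffer start at which the inhale occurs.
#' @param cfg A [stimulus_config()] (supplies `fade`).
#' @return The faded [audio_buffer()].
#' @export
apply_early_inhale_fadeout <- function(audio, inhale_time, cfg = stimulus_config()) {
  sr <- audio$sample_rate
  n <- nrow(audio$samples)
  stopifnot(inhale_time >= 0, inhale_time <= n / sr)
  ts <- (seq_len(n) - 1) / sr
  gain <- pmin(pmax(1 - (ts - inhale_time) / cfg$fade, 0), 1)
  audio$samples <- audio$samples * gain
  audio
}

#' Spatial radius of the nature scene
#'
#' Smooth periodic map from breathing phase to the radius of the circle on
#' which the eight wind-blown-leaves sources sit: one expansion/contraction
#' per breath cycle, bounded by `[r_min, r_max]`. Default expands on inhale
#' (radius maximal at phase 0).
#'
#' @param phase Phase in degrees (vectorised).
#' @param cfg A [stimulus_config()].
#' @return Radius values in `[r_min, r_max]`.
#' @export
nature_radius <- function(phase, cfg = stimulus_config()) {
  c01 <- (1 + cos(deg2rad(phase))) / 2
  if (cfg$radius_expand_on == "exhale") c01 <- 1 - c01
  cfg$r_min + (cfg$r_max - cfg$r_min) * c01
}

#' Azimuths of the eight nature sources
#'
#' @return Eight equidistant azimuths on a circle: 0, 45, ..., 315 degrees.
#' @export
nature_azimuths <- function() seq(0, 315, by = 45)

# Equal-power stereo pan: pan in [-1, 1] -> c(gainL, gainR).
pan_gains <- function(pan) {
  th <- (pan + 1) * pi / 4
  cbind(cos(th), sin(th))
}

# Procedural nature stems (synthetic stand-ins for the original field
# recordings): band-shaped noise for leaves and rain, decaying sines for
# chimes, swept sine chirps for birds.
render_nature_stimulus <- function(control, cfg = stimulus_config(), seed = 1) {
  sr <- cfg$sample_rate
  dur <- max(control$time) + 1 / cfg$control_rate
  n <- ceiling(dur * sr)
  ts <- (seq_len(n) - 1) / sr
  radius <- approx(control$time, control$radius, xout = ts, rule = 2)$y
  left <- numeric(n)
  right <- numeric(n)
  az <- nature_azimuths()
  for (k in seq_along(az)) {
    src <- generate_pink_noise(n, seed = seed * 100 + k, sample_rate = sr)
    cutoff <- 600 + 350 * k
    x <- onepole_tv(src$samples[, 1], rep(cutoff_to_coef(cutoff, sr), n))
    lfo <- 0.6 + 0.4 * sin(2 * pi * (0.05 + 0.013 * k) * ts + k)
    x <- x * lfo * 0.25
    pan <- radius * sin(deg2rad(az[k]))
    th <- (pan + 1) * pi / 4
    left <- left + x * cos(th)
    right <- right + x * sin(th)
  }
  extras <- with_seed(seed, {
    chime_t <- cumsum(rexp(max(3, ceiling(dur / 8)), rate = 1 / 8))
    chime_p <- sample(c(76, 79, 81, 84, 88), length(chime_t), replace = TRUE)
    bird_t <- cumsum(rexp(max(3, ceiling(dur / 10)), rate = 1 / 10))
    list(chime_t = chime_t, chime_p = chime_p, bird_t = bird_t,
         rain = rnorm(n))
  })
  chimes <- render_notes(
    tibble(onset = extras$chime_t[extras$chime_t < dur - 1],
           duration = 1.5, pitch = extras$chime_p[extras$chime_t < dur - 1],
           velocity = 0.25, role = "chime"),
    dur, sr
  )
  rain <- (extras$rain - onepole_tv(extras$rain, rep(cutoff_to_coef(1500, sr), n))) * 0.05
  birds <- numeric(n)
  for (bt in extras$bird_t[extras$bird_t < dur - 0.5]) {
    m <- floor(0.25 * sr)
    tt <- (seq_len(m) - 1) / sr
    chirp <- 0.12 * sin(2 * pi * (2500 * tt + 2000 * tt^2)) * sin(pi * tt / 0.25)^2
    i0 <- floor(bt * sr) + 1
    idx <- i0:(i0 + m - 1)
    birds[idx] <- birds[idx] + chirp
  }
  gl <- pan_gains(0.35); gb <- pan_gains(-0.5); gr <- pan_gains(0.1)
  left <- left + chimes * gl[1] + birds * gb[1] + rain * gr[1]
  right <- right + chimes * gl[2] + birds * gb[2] + rain * gr[2]
  normalize_peak(audio_buffer(cbind(left, right), sr))
}

# Music family: breath-noise bed plus one phrase per exhale, faded out when
# the next inhale arrives before the phrase ends.
render_music_stimulus <- function(control, cfg = stimulus_config(), seed = 1) {
  sr <- cfg$sample_rate
  dur <- max(control$time) + 1 / cfg$control_rate
  n <- ceiling(dur * sr)
  noise <- generate_pink_noise(n, seed = seed, sample_rate = sr)
  bed <- render_noise_stimulus(control, noise, cfg)
  phi <- control$phase
  split <- cfg$inhale_end_phase
  exhale_starts <- which(diff(phi >= split) == 1) + 1
  inhale_starts <- which(diff(phi) < -180) + 1    # wrap past 360 -> inhale
  phrase <- numeric(n)
  for (i in exhale_starts) {
    t0 <- control$time[i]
    nxt <- inhale_starts[inhale_starts > i]
    t_inhale <- if (length(nxt)) control$time[nxt[1]] else dur
    period <- 3 * (t_inhale - t0) / 2   # exhale is 2/3 of the cycle
    notes <- compose_music_phrase(period, cfg)
    stem_dur <- min(2 * period, dur - t0)
    if (stem_dur <= 0.05) next
    stem <- render_notes(notes, stem_dur, sr)
    stem_buf <- audio_buffer(stem, sr)
    if (t_inhale - t0 < period * 2 / 3) {
      stem_buf <- apply_early_inhale_fadeout(stem_buf, t_inhale - t0, cfg)
    }
    i0 <- floor(t0 * sr) + 1
    idx <- i0:min(i0 + length(stem) - 1, n)
    phrase[idx] <- phrase[idx] + stem_buf$samples[seq_along(idx), 1]
  }
  out <- bed$samples * cfg$music_noise_gain + cbind(phrase, phrase) * 0.5
  normalize_peak(audio_buffer(out, sr))
}

#' Render a stimulus family from a phase trajectory
#'
#' Top-level renderer: builds the breathing envelope from the stimulus phase
#' trajectory and dispatches to the noise, nature or music renderer. All
#' renders are deterministic given `(phase_traj, cfg, seed)`.
#'
#' @param phase_traj Tibble with columns `time`, `phase` at the control rate
#'   (e.g. the `trace` of a [closed_loop_session()], using `stim_phase`).
#' @param family `"noise"`, `"nature"` or `"music"`.
#' @param cfg A [stimulus_config()].
#' @param seed Integer seed for the noise generators.
#' @return A stereo [audio_buffer()], peak-limited to 0.99.
#' @export
render_stimulus <- function(phase_traj, family = c("noise", "nature", "music"),
                            cfg = stimulus_config(), seed = 1) {
  family <- match.arg(family)
  control <- breath_envelope(phase_traj, cfg)
  if (family == "noise") {
    n <- ceiling((max(control$time) + 1 / cfg$control_rate) * cfg$sample_rate)
    noise <- generate_pink_noise(n, seed = seed, sample_rate = cfg$sample_rate)
    render_noise_stimulus(control, noise, cfg)
  } else if (family == "nature") {
    render_nature_stimulus(control, cfg, seed)
  } else {
    render_music_stimulus(control, cfg, seed)
  }
}
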