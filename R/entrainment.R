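#' Coupling configuration for the stimulus oscillator
#'
#' Parameters of the Kuramoto phase coupling, the frequency-adaptation
#' channel, and the synchronization-gated phase delay.
#'
#' @param coupling Kuramoto coupling strength K, 1/seconds. Default 0.5.
#' @param dt Integration step in seconds (explicit Euler). Default 0.01.
#' @param freq_adapt Frequency-adaptation gain (1/seconds): the oscillator's
#'   frequency relaxes toward the breather's observed frequency at this rate.
#'   Default 0.2.
#' @param delay_max Upper bound of the gated phase delay, degrees. Default 50.
#' @param delay_gate `"linear"` (delay grows with synchronization R) or
#'   `"inverse"` (delay shrinks with R).
#' @param sync_window Length in seconds of the trailing window of phase pairs
#'   over which synchronization is measured. Default 15.
#' @return A list of class `coupling_config`.
#' @export
coupling_config <- function(coupling = 0.5, dt = 0.01, freq_adapt = 0.2,
                            delay_max = 50, delay_gate = c("linear", "inverse"),
                            sync_window = 15) {
  delay_gate <- match.arg(delay_gate)
  stopifnot(coupling >= 0, dt > 0, freq_adapt >= 0,
            delay_max >= 0, delay_max < 360, sync_window > 0)
  structure(
    list(coupling = coupling, dt = dt, freq_adapt = freq_adapt,
         delay_max = delay_max, delay_gate = delay_gate,
         sync_window = sync_window),
    class = "coupling_config"
  )
}

#' Create a stimulus oscillator
#'
#' @param natural_freq Natural frequency in Hz (breath cycles per second).
#' @param phase Initial phase in degrees.
#' @return A list of class `oscillator` with fields `phase`, `natural_freq`,
#'   `current_freq`.
#' @export
oscillator <- function(natural_freq = 0.2, phase = 0) {
  stopifnot(natural_freq > 0)
  structure(
    list(phase = wrap360(phase), natural_freq = natural_freq,
         current_freq = natural_freq),
    class = "oscillator"
  )
}

#' One Kuramoto update of the stimulus oscillator
#'
#' Explicit-Euler step of `dtheta/dt = omega + K sin(theta_target - theta)`
#' with the target phase `theta_target = breather_phase - target_offset`:
#' a positive offset makes the stimulus trail the breather by that angle,
#' which is how the gated phase delay steers an entrained breather. When
#' `breather_freq` is supplied the oscillator's frequency additionally relaxes
#' toward it at rate `cfg$freq_adapt`, giving the smooth tempo adaptation of
#' the biofeedback loop; with `phase_coupled = FALSE` only this frequency
#' channel acts (tempo-only alignment).
#'
#' @param stim An [oscillator()].
#' @param breather_phase Breather phase in degrees.
#' @param cfg A [coupling_config()].
#' @param target_offset Degrees by which the stimulus target trails the
#'   breather (0 for plain phase alignment).
#' @param breather_freq Observed breather frequency in Hz, or `NULL` to leave
#'   the frequency untouched.
#' @param phase_coupled Logical; if `FALSE` the sine coupling term is skipped.
#' @return The updated `oscillator`.
#' @export
kuramoto_step <- function(stim, breather_phase, cfg = coupling_config(),
                          target_offset = 0, breather_freq = NULL,
                          phase_coupled = TRUE) {
  dphase <- 360 * stim$current_freq * cfg$dt
  if (phase_coupled && cfg$coupling > 0) {
    target <- breather_phase - target_offset
    dphase <- dphase +
      rad2deg(cfg$coupling * sin(deg2rad(target - stim$phase))) * cfg$dt
  }
  stim$phase <- wrap360(stim$phase + dphase)
  if (!is.null(breather_freq) && cfg$freq_adapt > 0) {
    stim$current_freq <- stim$current_freq +
      cfg$freq_adapt * (breather_freq - stim$current_freq) * cfg$dt
  }
  stim
}

#' Circular mean resultant length of the phase difference
#'
#' `R = |mean(exp(i (phi_breath - phi_stim)))|`: 1 when the two phase vectors
#' keep a fixed relation (locked), near 0 when the difference is uniformly
#' spread. Invariant under a common rotation of both vectors.
#'
#' @param breather_phase,stim_phase Equal-length phase vectors in degrees.
#' @return A number in `[0, 1]`.
#' @export
mean_vector_length <- function(breather_phase, stim_phase) {
  if (length(breather_phase) == 0) {
    abort("empty synchronization window", class = "breathsync_sync_error")
  }
  stopifnot(length(breather_phase) == length(stim_phase))
  d <- deg2rad(breather_phase - stim_phase)
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

#' Synchronization-gated phase delay
#'
#' Maps the synchronization level R to a delay angle in `[0, delay_max]`.
#' The default gate is linear (`R * delay_max`): the delay is only applied
#' once the loop is entrained, so it can pull breathing. An `"inverse"` gate
#' (`(1 - R) * delay_max`) is available.
#'
#' @param R Mean resultant length in `[0, 1]`.
#' @param cfg A [coupling_config()].
#' @return Delay in degrees, clamped to `[0, cfg$delay_max]`; vectorised.
#' @export
phase_delay <- function(R, cfg = coupling_config()) {
  if (any(R < 0 | R > 1)) {
    abort("R must lie in [0, 1]", class = "breathsync_sync_error")
  }
  d <- switch(cfg$delay_gate,
    linear = R * cfg$delay_max,
    inverse = (1 - R) * cfg$delay_max
  )
  pmin(pmax(d, 0), cfg$delay_max)
}

#' Target phase offset for an alignment mode
#'
#' `silence` and `tempo_only` disable phase coupling (offset `NA`, see
#' `coupled`); `phase_and_tempo` aligns exactly (offset 0); `phase_delayed`
#' applies the synchronization-gated delay magnitude from [phase_delay()].
#'
#' @param mode One of `"silence"`, `"tempo_only"`, `"phase_and_tempo"`,
#'   `"phase_delayed"`.
#' @param R Current mean resultant length (used only for `phase_delayed`).
#' @param cfg A [coupling_config()].
#' @return A list with `coupled` (logical: is the phase channel active?) and
#'   `offset` (degrees the stimulus target trails the breather; `NA` when
#'   uncoupled).
#' @export
target_offset <- function(mode, R = 0, cfg = coupling_config()) {
  mode <- match.arg(mode, alignment_modes())
  switch(mode,
    silence = list(coupled = FALSE, offset = NA_real_),
    tempo_only = list(coupled = FALSE, offset = NA_real_),
    phase_and_tempo = list(coupled = TRUE, offset = 0),
    phase_delayed = list(coupled = TRUE, offset = phase_delay(R, cfg))
  )
}
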