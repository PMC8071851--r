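#' The four alignment modes of a trial
#'
#' @return Character vector `c("silence", "tempo_only", "phase_and_tempo",
#'   "phase_delayed")`.
#' @export
alignment_modes <- function() {
  c("silence", "tempo_only", "phase_and_tempo", "phase_delayed")
}

#' Build a trial schedule
#'
#' The default reproduces the 8-minute trial timeline: 1 min of silence, then
#' the stimulus tempo-aligned for 1 min, phase- and tempo-aligned for 3 min,
#' and phase-delayed for 3 min. Boundaries are cumulative sums computed once,
#' so they are bit-reproducible from the configuration.
#'
#' @param segments Optional tibble/data.frame with columns `mode` and
#'   `duration` (seconds); defaults to the standard four-segment trial.
#' @return A tibble of class `session_schedule` with columns `mode`,
#'   `duration`, `start`, `end` and attribute `total`.
#' @export
build_schedule <- function(segments = NULL) {
  if (is.null(segments)) {
    segments <- tibble(
      mode = alignment_modes(),
      duration = c(60, 60, 180, 180)
    )
  }
  segments <- as_tibble(segments)
  stopifnot(all(c("mode", "duration") %in% names(segments)))
  if (any(segments$duration <= 0)) {
    abort("segment durations must be positive", class = "breathsync_schedule_error")
  }
  if (!all(segments$mode %in% alignment_modes())) {
    abort("unknown alignment mode", class = "breathsync_schedule_error")
  }
  ends <- cumsum(segments$duration)
  out <- segments |>
    mutate(start = ends - .data$duration, end = ends)
  structure(out, total = ends[length(ends)],
            class = c("session_schedule", class(out)))
}

#' Total duration of a schedule
#' @param schedule A [build_schedule()] result.
#' @return Seconds.
#' @export
schedule_total <- function(schedule) attr(schedule, "total")

#' Alignment mode at a time point
#'
#' Segments are half-open intervals `[start, end)`: a boundary instant belongs
#' to the later segment.
#'
#' @param schedule A [build_schedule()] result.
#' @param t Time(s) in seconds, each in `[0, total)`.
#' @return Character vector of modes, one per element of `t`.
#' @export
mode_at <- function(schedule, t) {
  total <- schedule_total(schedule)
  if (any(t < 0 | t >= total)) {
    abort("`t` outside [0, total)", class = "breathsync_schedule_error")
  }
  idx <- findInterval(t, schedule$start)
  schedule$mode[idx]
}
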