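# Run manifests: every run writes config hash + seed + package version so
# identical (config, seed) pairs are recognisably identical runs.
write_manifest <- function(cfg, outputs, path) {
  hashable <- cfg
  hashable$out_dir <- NULL
  manifest <- list(
    package = "breathsync",
    version = as.character(utils::packageVersion("breathsync")),
    seed = cfg$seed,
    family = cfg$family,
    config_hash = rlang::hash(hashable),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a closed-loop session to files
#'
#' Runs [closed_loop_session()] under the configuration and writes the onset
#' log (`events.txt`, drop-in keypress-log format), the control-rate trace
#' (`trace.csv`) and a manifest (`manifest.json`) into `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return The `session_log`, invisibly.
#' @export
run_simulate <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- closed_loop_session(
    params = cfg$breather, schedule = cfg$schedule,
    tracker_cfg = cfg$tracker, coupling_cfg = cfg$coupling,
    stim_cfg = cfg$stimulus, seed = cfg$seed
  )
  ev_path <- file.path(cfg$out_dir, "events.txt")
  tr_path <- file.path(cfg$out_dir, "trace.csv")
  write_keypress_log(log$events, ev_path)
  write.csv(log$trace, tr_path, row.names = FALSE)
  write_manifest(cfg, list(events = ev_path, trace = tr_path),
                 file.path(cfg$out_dir, "manifest.json"))
  invisible(log)
}

#' Render a session's stimulus to WAV
#'
#' Rebuilds the stimulus phase trajectory from a session log (its trace, or a
#' keypress log re-tracked through the breath tracker) and renders the
#' configured stimulus family to a stereo WAV file.
#'
#' @param cfg A [run_config()].
#' @param log A `session_log`, a trace tibble with `time` and `stim_phase`
#'   columns, or a path to a keypress log.
#' @param duration Seconds to render (default: full trace; capped for
#'   keypress-log input at the log's span).
#' @return Path of the written WAV, invisibly.
#' @export
run_render <- function(cfg = run_config(), log, duration = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- if (inherits(log, "session_log")) {
    log$trace
  } else if (is.character(log)) {
    events <- read_keypress_log(log)
    track_breathing(events, cfg$tracker,
                    dt = 1 / cfg$stimulus$control_rate) |>
      dplyr::rename(stim_phase = "phase")
  } else {
    log
  }
  if (!is.null(duration)) trace <- trace[trace$time < duration, ]
  phase_traj <- tibble(time = trace$time, phase = trace$stim_phase)
  buf <- render_stimulus(phase_traj, family = cfg$family,
                         cfg = cfg$stimulus, seed = cfg$seed)
  wav_path <- file.path(cfg$out_dir, paste0("stimulus_", cfg$family, ".wav"))
  write_wav(buf, wav_path)
  write_manifest(cfg, list(wav = wav_path),
                 file.path(cfg$out_dir, "render_manifest.json"))
  invisible(wav_path)
}

#' Analyze keypress logs to tidy tables
#'
#' Runs the rate/ratio pipeline on one or more keypress logs and writes a
#' tidy grid CSV (one row per trial x grid point), a JSON fit summary, and a
#' manifest.
#'
#' @param cfg A [run_config()]; `cfg$analysis` controls kind, duration, grid
#'   rate and window.
#' @param logs Character vector of keypress-log paths, or a single
#'   `session_log`.
#' @param conditions Optional condition label per log (recycled).
#' @return A list with `series` (long tibble) and `fit` (a `growth_fit`),
#'   invisibly.
#' @export
run_analyze <- function(cfg = run_config(), logs, conditions = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- cfg$analysis
  if (inherits(logs, "session_log")) {
    event_sets <- list(logs$events)
    ids <- "session"
  } else {
    event_sets <- lapply(logs, read_keypress_log)
    ids <- if (is.character(logs)) basename(logs) else as.character(seq_along(logs))
  }
  conditions <- conditions %||% rep("baseline", length(event_sets))
  series <- purrr::imap_dfr(event_sets, function(ev, i) {
    ts <- trial_series(ev, kind = a$kind, duration = a$duration,
                       grid_rate = a$grid_rate, window = a$window)
    tibble(trial = ids[[i]], condition = conditions[[i]],
           grid_time = ts$time, value = ts$value, log_value = ts$log_value,
           skipped_fraction = skipped_fraction(ts))
  })
  fit_input <- series |>
    dplyr::rename(time = "grid_time") |>
    select("trial", "condition", "time", "value")
  if (length(unique(fit_input$condition)) == 1) {
    fit_input$condition <- NULL
  }
  fit <- fit_growth(fit_input)
  csv_path <- file.path(cfg$out_dir, paste0("series_", a$kind, ".csv"))
  fit_path <- file.path(cfg$out_dir, paste0("fit_", a$kind, ".json"))
  write.csv(series, csv_path, row.names = FALSE)
  jsonlite::write_json(list(kind = a$kind, coefficients = tidy(fit),
                            summary = glance(fit)),
                       fit_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, list(series = csv_path, fit = fit_path),
                 file.path(cfg$out_dir, "analyze_manifest.json"))
  invisible(list(series = series, fit = fit))
}
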