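#' Read a keypress log
#'
#' Plain-text onset log: one event per line, `<timestamp_seconds>\tI|E`
#' (whitespace-separated; CRLF and blank lines tolerated). Unparseable lines
#' are skipped with a warning; out-of-order timestamps are rejected with a
#' warning and a count.
#'
#' @param path Log file path.
#' @return Tibble with columns `time` (seconds), `kind`
#'   (`"inhale"`/`"exhale"`).
#' @export
read_keypress_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty keypress log: ", path), class = "breathsync_io_error")
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  times <- numeric(0); kinds <- character(0)
  n_bad <- 0L; n_order <- 0L
  for (p in parts) {
    t <- suppressWarnings(as.numeric(p[1]))
    k <- if (length(p) >= 2) toupper(p[2]) else NA_character_
    if (is.na(t) || !(k %in% c("I", "E"))) {
      n_bad <- n_bad + 1L
      next
    }
    if (length(times) > 0 && t <= times[length(times)]) {
      n_order <- n_order + 1L
      next
    }
    times <- c(times, t)
    kinds <- c(kinds, if (k == "I") "inhale" else "exhale")
  }
  if (n_bad > 0) warn(sprintf("%d unparseable line(s) skipped in %s", n_bad, path))
  if (n_order > 0) warn(sprintf("%d out-of-order line(s) rejected in %s", n_order, path))
  tibble(time = times, kind = kinds)
}

#' Write a keypress log
#'
#' Inverse of [read_keypress_log()]; output is byte-stable for identical
#' inputs. Synthetic session logs written this way are drop-in replacements
#' for participant files.
#'
#' @param events Tibble with columns `time`, `kind`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypress_log <- function(events, path) {
  lines <- sprintf("%.6f\t%s", events$time,
                   ifelse(events$kind == "inhale", "I", "E"))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles the sub-configurations of a reproducible run. All defaults are
#' resolvable with no file at all; [read_run_config()] overlays a YAML file
#' on these defaults.
#'
#' @param tracker,coupling,stimulus,breather Sub-configuration objects.
#' @param schedule A [build_schedule()] result.
#' @param family Stimulus family: `"noise"`, `"nature"` or `"music"`.
#' @param analysis List with `kind`, `duration`, `grid_rate`, `window`.
#' @param seed Master seed.
#' @param out_dir Output directory for run artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tracker = tracker_config(),
                       coupling = coupling_config(),
                       stimulus = stimulus_config(),
                       breather = breather_params(),
                       schedule = build_schedule(),
                       family = c("noise", "nature", "music"),
                       analysis = list(kind = "rate", duration = 480,
                                       grid_rate = 0.1, window = 6),
                       seed = 1, out_dir = ".") {
  family <- match.arg(family)
  structure(
    list(tracker = tracker, coupling = coupling, stimulus = stimulus,
         breather = breather, schedule = schedule, family = family,
         analysis = analysis, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Any subset of fields may be given; the rest fall back to the defaults of
#' [run_config()]. The schedule is a list of `{mode, duration}` entries.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(ctor, field) {
    args <- y[[field]] %||% list()
    do.call(ctor, args)
  }
  schedule <- if (!is.null(y$schedule)) {
    build_schedule(purrr::map_dfr(y$schedule, as_tibble))
  } else {
    build_schedule()
  }
  run_config(
    tracker = take(tracker_config, "tracker"),
    coupling = take(coupling_config, "coupling"),
    stimulus = take(stimulus_config, "stimulus"),
    breather = take(breather_params, "breather"),
    schedule = schedule,
    family = y$family %||% "noise",
    analysis = utils::modifyList(
      list(kind = "rate", duration = 480, grid_rate = 0.1, window = 6),
      y$analysis %||% list()
    ),
    seed = y$seed %||% 1,
    out_dir = y$out_dir %||% "."
  )
}
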