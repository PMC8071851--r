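#' Plot a closed-loop session
#'
#' Three stacked panels over session time: breather vs stimulus phase,
#' synchronization (mean resultant length) with the gated delay, and the
#' stimulus frequency expressed in breaths/min, with the alignment-mode
#' boundaries marked.
#'
#' @param object A `session_log` from [closed_loop_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot session_log
#' @export
autoplot.session_log <- function(object, ...) {
  tr <- object$trace
  bounds <- object$schedule$start[-1]
  long <- bind_rows(
    tibble(time = tr$time, value = tr$R, panel = "synchronization R"),
    tibble(time = tr$time, value = tr$delay / 50, panel = "delay / 50 deg"),
    tibble(time = tr$time, value = tr$stim_freq * 60,
           panel = "stimulus rate (breaths/min)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Closed-loop biofeedback session") +
    ggplot2::theme_minimal()
}

#' Plot a trial series on the analysis grid
#'
#' @param object A `trial_series` from [trial_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_series
#' @export
autoplot.trial_series <- function(object, ...) {
  kind <- attr(object, "kind")
  ylab <- if (kind == "rate") "respiration rate (breaths/min)" else "exhale/inhale ratio"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = ylab,
                  title = sprintf("Respiration %s (%.1f%% of values skipped)",
                                  kind, skipped_fraction(object))) +
    ggplot2::theme_minimal()
}

#' Plot growth-fit coefficients
#'
#' Estimates with approximate 95% intervals per polynomial term (on the log
#' scale), faceted by condition when present.
#'
#' @param object A `growth_fit` from [fit_growth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  td <- tidy(object) |>
    tidyr::separate(.data$term, into = c("term", "condition"), sep = ":",
                    fill = "right") |>
    mutate(condition = ifelse(is.na(.data$condition), "(baseline)",
                              .data$condition))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "estimate (log scale)",
                  title = "Orthogonal-polynomial growth terms") +
    ggplot2::theme_minimal()
}
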