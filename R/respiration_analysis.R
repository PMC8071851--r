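#' Per-keypress intervals and per-cycle ratios
#'
#' Inter-onset times (IOTs) between consecutive keypresses, and the
#' exhale/inhale duration ratio for every complete cycle (inhale onset ->
#' exhale onset = inhale duration; exhale onset -> next inhale onset = exhale
#' duration). Cycles missing their exhale press yield no ratio.
#'
#' @param events Tibble with columns `time`, `kind`.
#' @return List with `iot` (tibble `time`, `value`; timestamped at the
#'   interval's end event) and `ratio` (tibble `time`, `value`; timestamped at
#'   the cycle midpoint).
#' @export
cycle_metrics <- function(events) {
  n <- nrow(events)
  if (n < 2) {
    return(list(iot = tibble(time = numeric(0), value = numeric(0)),
                ratio = tibble(time = numeric(0), value = numeric(0))))
  }
  iot <- tibble(time = events$time[-1], value = diff(events$time))
  rt <- numeric(0); rv <- numeric(0)
  for (i in seq_len(n - 2)) {
    if (events$kind[i] == "inhale" && events$kind[i + 1] == "exhale" &&
        events$kind[i + 2] == "inhale") {
      inhale_d <- events$time[i + 1] - events$time[i]
      exhale_d <- events$time[i + 2] - events$time[i + 1]
      rt <- c(rt, (events$time[i] + events$time[i + 2]) / 2)
      rv <- c(rv, exhale_d / inhale_d)
    }
  }
  list(iot = iot, ratio = tibble(time = rt, value = rv))
}

#' Sliding median over a value stream
#'
#' Median over each contiguous span of `k` values (a 6-keypress window bounds
#' 5 IOT values, so the default is `k = 5`); only full windows are emitted,
#' timestamped at the window's median time.
#'
#' @param stream Tibble with columns `time`, `value`.
#' @param k Window length in values.
#' @return Tibble with columns `time`, `value`; empty when the stream is
#'   shorter than `k`.
#' @export
sliding_median <- function(stream, k = 5) {
  n <- nrow(stream)
  if (n < k) return(tibble(time = numeric(0), value = numeric(0)))
  idx <- seq_len(n - k + 1)
  tibble(
    time = vapply(idx, function(i) median(stream$time[i:(i + k - 1)]), 0),
    value = vapply(idx, function(i) median(stream$value[i:(i + k - 1)]), 0)
  )
}

#' Respiration rate timeseries from onset events
#'
#' Breaths/min over a sliding 6-keypress window, computed from full
#' inhale-to-inhale cycle intervals inside the window (ratio-independent):
#' `rate = 60 / median(full-cycle intervals)`. Windows with fewer than two
#' inhale onsets fall back to twice the median mixed half-cycle interval.
#'
#' @param events Tibble with columns `time`, `kind`.
#' @param window Keypresses per window (default 6).
#' @return Tibble with columns `time` (window median time), `value`
#'   (breaths/min).
#' @export
rate_series <- function(events, window = 6) {
  n <- nrow(events)
  if (n < window) return(tibble(time = numeric(0), value = numeric(0)))
  idx <- seq_len(n - window + 1)
  out_t <- numeric(length(idx)); out_v <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    tw <- events$time[i:(i + window - 1)]
    kw <- events$kind[i:(i + window - 1)]
    inh <- tw[kw == "inhale"]
    per <- if (length(inh) >= 2) median(diff(inh)) else 2 * median(diff(tw))
    out_t[j] <- median(tw)
    out_v[j] <- 60 / per
  }
  tibble(time = out_t, value = out_v)
}

#' Discard values deviating from the previous window
#'
#' A value is treated as an erroneous press and discarded when it deviates
#' from the mean of the previous window (the trailing `width` accepted
#' values) by more than `nsd` times that window's sample SD. The first window
#' is never discarded. When the previous window is constant (SD below `eps`)
#' any deviation above `eps` is discarded.
#'
#' @param stream Tibble with columns `time`, `value`.
#' @param width Window length in values (5 values = one 6-keypress window).
#' @param nsd SD multiple defining an outlier (default 5).
#' @param eps Degeneracy guard for constant windows.
#' @return The kept rows, with attribute `skipped_fraction` (percent of
#'   values discarded); read it with [skipped_fraction()].
#' @export
outlier_filter <- function(stream, width = 5, nsd = 5, eps = 1e-9) {
  n <- nrow(stream)
  keep <- logical(n)
  acc <- numeric(0)
  for (i in seq_len(n)) {
    v <- stream$value[i]
    if (length(acc) < width) {
      ok <- TRUE
    } else {
      w <- tail(acc, width)
      m <- mean(w); s <- sd(w)
      ok <- if (s < eps) abs(v - m) <= eps else abs(v - m) <= nsd * s
    }
    keep[i] <- ok
    if (ok) acc <- c(acc, v)
  }
  out <- stream[keep, ]
  attr(out, "keep") <- keep
  attr(out, "skipped_fraction") <- 100 * sum(!keep) / max(n, 1)
  out
}

#' Percent of values discarded by the outlier filter
#' @param x An [outlier_filter()] or [trial_series()] result.
#' @return Percent in `[0, 100]`.
#' @export
skipped_fraction <- function(x) attr(x, "skipped_fraction")

#' Resample a stream onto the analysis grid
#'
#' Linear interpolation onto a regular grid (default 0.1 Hz: t = 0, 10, ...,
#' 470 s — 48 samples for an 8-minute trial); the nearest value is held
#' beyond the first/last observation.
#'
#' @param stream Tibble with columns `time`, `value` (at least 2 rows).
#' @param rate Grid rate in Hz.
#' @param duration Trial duration in seconds.
#' @return Tibble with columns `time`, `value` and `duration * rate` rows.
#' @export
resample_series <- function(stream, rate = 0.1, duration = 480) {
  if (nrow(stream) < 2) {
    abort("need at least 2 surviving points to resample",
          class = "breathsync_analysis_error")
  }
  grid <- seq(0, by = 1 / rate, length.out = round(duration * rate))
  tibble(time = grid,
         value = approx(stream$time, stream$value, xout = grid, rule = 2)$y)
}

#' Orthonormal polynomial basis
#'
#' Gram-Schmidt (QR) orthonormalisation of the Vandermonde matrix of the grid
#' index, giving columns for polynomial degrees 0..`degree` with
#' `t(B) %*% B = I`. Signs are fixed so each column ends positive (the linear
#' column is increasing).
#'
#' @param n Grid length (default 48).
#' @param degree Highest polynomial degree (default 4).
#' @return An `n x (degree + 1)` matrix, columns named `degree0` ...
#' @export
orthogonal_basis <- function(n = 48, degree = 4) {
  stopifnot(n > degree)
  V <- outer(seq_len(n) / n, 0:degree, `^`)
  Q <- qr.Q(qr(V))
  s <- sign(Q[n, ]); s[s == 0] <- 1
  Q <- sweep(Q, 2, s, `*`)
  colnames(Q) <- paste0("degree", 0:degree)
  Q
}

#' Fit an orthogonal-polynomial growth curve
#'
#' Least-squares fit of the log-transformed series on a fourth-order
#' orthogonal polynomial in time. The degree-0 column is rescaled to a plain
#' intercept (constant 1), so for a constant series the intercept is the log
#' of that constant; higher-degree columns stay orthonormal. When the series
#' carries a `condition` column, condition interactions with every time term
#' are added (treatment coding against the first level), mirroring a
#' fixed-effect-of-condition growth model; participant-level random effects
#' are out of scope and can be fitted externally from [tidy_growth_table()].
#'
#' @param series Tibble with a positive `value` column; optionally `condition`
#'   and `trial` columns (each trial must contribute one full grid of rows, in
#'   grid order).
#' @param basis Basis matrix from [orthogonal_basis()]; defaults to one
#'   matching the per-trial grid length.
#' @param degree Polynomial degree used when `basis` is `NULL`.
#' @return An object of class `growth_fit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_growth <- function(series, basis = NULL, degree = 4) {
  bad <- which(series$value <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive values at index ", paste(head(bad, 5), collapse = ", "),
                 "; log transform undefined"),
          class = "breathsync_analysis_error")
  }
  n_total <- nrow(series)
  n_trials <- if ("trial" %in% names(series)) {
    length(unique(series$trial))
  } else 1L
  n_grid <- n_total / n_trials
  if (n_grid != round(n_grid)) {
    abort("each trial must contribute the same number of grid rows",
          class = "breathsync_analysis_error")
  }
  basis <- basis %||% orthogonal_basis(n_grid, degree)
  B <- basis
  B[, 1] <- 1   # intercept on the plain log scale
  X <- B[rep(seq_len(n_grid), n_trials), , drop = FALSE]
  colnames(X) <- c("intercept", colnames(basis)[-1])
  logv <- log(series$value)
  if ("condition" %in% names(series)) {
    cond <- factor(series$condition)
    lv <- levels(cond)
    blocks <- list(X)
    for (l in lv[-1]) {
      Xi <- X * as.numeric(cond == l)
      colnames(Xi) <- paste0(colnames(X), ":", l)
      blocks <- c(blocks, list(Xi))
    }
    X <- do.call(cbind, blocks)
  } else {
    cond <- NULL
  }
  fit <- lm(logv ~ 0 + X)
  names(fit$coefficients) <- sub("^X", "", names(fit$coefficients))
  structure(
    list(fit = fit, basis = basis, n_grid = n_grid, n_trials = n_trials,
         conditions = if (is.null(cond)) NULL else levels(cond)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> degree-%d orthogonal polynomial, %d trial(s) x %d grid points\n",
              ncol(x$basis) - 1, x$n_trials, x$n_grid))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a growth fit
#'
#' One row per model term: estimate, standard error, and the
#' normal-approximation z statistic and p value on the log scale.
#'
#' @param x A [fit_growth()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 1] / s[, 2],
    p.value = 2 * stats::pnorm(-abs(s[, 1] / s[, 2]))
  )
}

#' One-row summary of a growth fit
#'
#' @param x A [fit_growth()] result.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `sigma`, `nobs`, `df.residual`.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = length(s$residuals),
    df.residual = x$fit$df.residual
  )
}

#' Full rate/ratio pipeline for one trial
#'
#' Runs the complete extraction chain on one keypress log. The 5-SD rule is
#' applied to the raw streams (per-keypress IOTs, and for ratios additionally
#' the per-cycle ratios): an IOT flagged as deviant marks the press that ends
#' it as erroneous, and that press is removed before windowing. The cleaned
#' events are then smoothed over the sliding 6-keypress window and resampled
#' onto the 0.1 Hz analysis grid, with log-transformed values alongside.
#'
#' @param events Tibble with columns `time`, `kind`.
#' @param kind `"rate"` (breaths/min) or `"ratio"` (exhale/inhale).
#' @param duration Trial duration, seconds.
#' @param grid_rate Analysis grid rate, Hz.
#' @param window Keypresses per sliding window.
#' @return A tibble of class `trial_series` with columns `time`, `value`,
#'   `log_value`; attributes `kind` and `skipped_fraction` (percent of raw
#'   values discarded).
#' @export
trial_series <- function(events, kind = c("rate", "ratio"), duration = 480,
                         grid_rate = 0.1, window = 6) {
  kind <- match.arg(kind)
  width <- window - 1
  iot <- cycle_metrics(events)$iot
  iot_f <- outlier_filter(iot, width = width)
  bad_press <- which(!attr(iot_f, "keep")) + 1L
  ev <- if (length(bad_press)) events[-bad_press, ] else events
  if (kind == "rate") {
    stream <- rate_series(ev, window)
    skipped <- attr(iot_f, "skipped_fraction")
  } else {
    ratio <- cycle_metrics(ev)$ratio
    ratio_f <- outlier_filter(ratio, width = width)
    stream <- sliding_median(ratio_f, k = width)
    n_raw <- nrow(iot) + nrow(ratio)
    n_bad <- length(bad_press) + sum(!attr(ratio_f, "keep"))
    skipped <- 100 * n_bad / max(n_raw, 1)
  }
  grid <- resample_series(stream, rate = grid_rate, duration = duration)
  out <- grid |> mutate(log_value = log(.data$value))
  structure(out, kind = kind, skipped_fraction = skipped,
            class = c("trial_series", class(out)))
}

#' Long-format table for external mixed-model fitting
#'
#' Stacks per-trial grid series into the tidy long format (trial, condition,
#' grid time, value, log value, polynomial time terms) expected by external
#' mixed-effects fitters — the full random-effects structure over
#' participants is deliberately delegated.
#'
#' @param trials Tibble with columns `trial`, `condition` and a list-column
#'   `events` of onset tibbles.
#' @param kind `"rate"` or `"ratio"`.
#' @param ... Passed to [trial_series()].
#' @return A long tibble with one row per trial x grid point, including
#'   columns `degree0` ... `degree4`.
#' @export
tidy_growth_table <- function(trials, kind = c("rate", "ratio"), ...) {
  kind <- match.arg(kind)
  purrr::pmap_dfr(trials, function(trial, condition, events, ...) {
    ts <- trial_series(events, kind = kind, ...)
    B <- orthogonal_basis(nrow(ts))
    bind_cols(
      tibble(trial = trial, condition = condition,
             grid_time = ts$time, value = ts$value, log_value = ts$log_value),
      as_tibble(B)
    )
  })
}
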