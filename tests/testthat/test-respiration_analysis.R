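test_that("cycle metrics recover IOTs and exhale:inhale ratios from event streams", {
  ev <- tibble::tibble(time = c(0, 2, 6, 8, 12),
                       kind = c("inhale", "exhale", "inhale", "exhale", "inhale"))
  cm <- cycle_metrics(ev)
  expect_equal(cm$iot$value, c(2, 4, 2, 4))
  expect_equal(cm$iot$time, c(2, 6, 8, 12))
  expect_equal(cm$ratio$value, c(2, 2))

  # a cycle missing its exhale press yields no ratio, IOTs unaffected
  ev2 <- tibble::tibble(time = c(0, 2, 6, 12, 14, 18),
                        kind = c("inhale", "exhale", "inhale", "inhale",
                                 "exhale", "inhale"))
  cm2 <- cycle_metrics(ev2)
  expect_equal(nrow(cm2$iot), 5)
  expect_equal(cm2$ratio$value, c(2, 2))  # cycles 1 and 3 only

  empty <- cycle_metrics(tibble::tibble(time = 1, kind = "inhale"))
  expect_equal(nrow(empty$iot), 0)
})

test_that("sliding median smooths full windows only and resists outliers", {
  s <- tibble::tibble(time = 1:10, value = rep(3, 10))
  sm <- sliding_median(s, k = 5)
  expect_equal(nrow(sm), 6)
  expect_true(all(sm$value == 3))
  expect_equal(sm$time[1], 3)  # window median time

  spiked <- tibble::tibble(time = 1:5, value = c(2, 2, 50, 2, 2))
  expect_equal(sliding_median(spiked, k = 5)$value, 2)

  short <- sliding_median(tibble::tibble(time = 1:3, value = 1:3), k = 5)
  expect_equal(nrow(short), 0)
})

test_that("windowed rate is 10 breaths/min for constant 6-second cycles", {
  ev <- make_periodic_events(rate = 10, ratio = 2, duration = 120)
  rs <- rate_series(ev)
  expect_true(all(abs(rs$value - 10) < 1e-9))
  expect_equal(nrow(rs), nrow(ev) - 5)
})

test_that("the 5-SD rule discards exactly the planted deviants", {
  base <- withr::with_seed(9, rnorm(30, mean = 3, sd = 0.1))
  vals <- c(base[1:20], 3 + 10 * 0.1 * 5, base[21:30])  # + well past 5 SD
  s <- tibble::tibble(time = seq_along(vals), value = vals)
  f <- outlier_filter(s, width = 5)
  expect_equal(sum(!attr(f, "keep")), 1)
  expect_false(attr(f, "keep")[21])
  expect_equal(skipped_fraction(f), 100 / length(vals))

  clean <- make_periodic_events(rate = 10, ratio = 2, duration = 240)
  iot <- cycle_metrics(clean)$iot
  expect_equal(skipped_fraction(outlier_filter(iot)), 0)

  # degenerate constant window: any deviation beyond epsilon is discarded
  const <- tibble::tibble(time = 1:7, value = c(rep(2, 6), 2.001))
  expect_equal(sum(!attr(outlier_filter(const, width = 5), "keep")), 1)
})

test_that("resampling yields the 48-point 0.1 Hz grid with exact linear behaviour", {
  s <- tibble::tibble(time = seq(0, 480, by = 7), value = 5)
  g <- resample_series(s)
  expect_equal(nrow(g), 48)
  expect_equal(g$time, seq(0, 470, by = 10))
  expect_true(all(g$value == 5))

  ramp <- tibble::tibble(time = c(0, 480), value = c(1, 25))
  gr <- resample_series(ramp)
  expect_equal(gr$value, 1 + 24 * gr$time / 480, tolerance = 1e-12)

  expect_error(resample_series(s[1, ]), class = "breathsync_analysis_error")
})

test_that("the orthogonal basis is orthonormal with the expected column shapes", {
  B <- orthogonal_basis(48, 4)
  expect_lt(max(abs(crossprod(B) - diag(5))), 1e-10)
  expect_equal(ncol(B), 5)
  expect_lt(diff(range(B[, 1])), 1e-12)            # degree 0 constant
  expect_true(all(diff(B[, 2]) > 0))               # linear, increasing
  expect_lt(abs(mean(B[, 2])), 1e-12)              # zero-mean
  # agrees with the standard orthogonal-polynomial construction up to sign
  P <- cbind(1 / sqrt(48), stats::poly(1:48, 4))
  expect_lt(max(abs(abs(crossprod(B, P)) - diag(5))), 1e-8)
})

test_that("growth fits recover exact signals and flag non-positive input", {
  B <- orthogonal_basis(48, 4)
  const <- tibble::tibble(time = seq(0, 470, 10), value = rep(4.2, 48))
  f <- fit_growth(const)
  co <- coef(f$fit)
  expect_equal(unname(co[1]), log(4.2), tolerance = 1e-10)
  expect_true(all(abs(co[-1]) < 1e-10))

  X <- B; X[, 1] <- 1
  beta <- c(2, -0.4, 0.2, -0.1, 0.05)
  synth <- tibble::tibble(time = seq(0, 470, 10),
                          value = exp(as.numeric(X %*% beta)))
  f2 <- fit_growth(synth, basis = B)
  expect_equal(unname(coef(f2$fit)), beta, tolerance = 1e-8)

  bad <- const; bad$value[7] <- -1
  expect_error(fit_growth(bad), "index 7",
               class = "breathsync_analysis_error")
})

test_that("coefficient standard errors match the analytic least-squares form", {
  B <- orthogonal_basis(48, 4)
  X <- B; X[, 1] <- 1
  beta <- c(2, -0.3, 0.1, 0, 0)
  sigma <- 0.05
  analytic <- sigma * sqrt(diag(solve(crossprod(X))))
  ests <- withr::with_seed(21, {
    replicate(200, {
      v <- exp(as.numeric(X %*% beta) + rnorm(48, 0, sigma))
      coef(fit_growth(tibble::tibble(value = v), basis = B)$fit)
    })
  })
  mc_se <- apply(ests, 1, sd)
  expect_true(all(abs(mc_se - analytic) / analytic < 0.2))
  # and the reported model SEs agree with the analytic values on average
  one <- withr::with_seed(22, {
    v <- exp(as.numeric(X %*% beta) + rnorm(48, 0, sigma))
    tidy(fit_growth(tibble::tibble(value = v), basis = B))
  })
  expect_equal(unname(one$std.error), unname(analytic), tolerance = 0.5)
})

test_that("condition interactions add one block of terms per non-reference level", {
  B <- orthogonal_basis(24, 4)
  X <- B; X[, 1] <- 1
  mk <- function(shift) exp(as.numeric(X %*% c(2 + shift, -0.2, 0, 0, 0)))
  series <- tibble::tibble(
    trial = rep(c("a", "b"), each = 24),
    condition = rep(c("baseline", "noise"), each = 24),
    value = c(mk(0), mk(0.5))
  )
  f <- fit_growth(series, basis = B)
  td <- suppressWarnings(tidy(f))  # exact fit: lm warns about its sigma
  expect_equal(nrow(td), 10)
  expect_equal(unname(td$estimate[td$term == "intercept:noise"]), 0.5,
               tolerance = 1e-8)
  expect_equal(unname(td$estimate[td$term == "intercept"]), 2,
               tolerance = 1e-8)
})

test_that("the full pipeline is deterministic and clean logs lose nothing", {
  ev <- simulate_breather_events(breather_params(entrain_gain = 0), seed = 5)
  a <- trial_series(ev, "rate")
  b <- trial_series(ev, "rate")
  expect_identical(a, b)
  fa <- fit_growth(a); fb <- fit_growth(b)
  expect_identical(coef(fa$fit), coef(fb$fit))

  clean <- make_periodic_events(rate = 10, ratio = 2, duration = 480)
  ts <- trial_series(clean, "rate")
  expect_equal(skipped_fraction(ts), 0)
  expect_equal(nrow(ts), 48)
  expect_true(all(abs(ts$value - 10) < 1e-9))
  tr <- trial_series(clean, "ratio")
  expect_true(all(abs(tr$value - 2) < 1e-9))
})

test_that("injected double-presses are caught by the outlier stage", {
  # a ratio-1 breather keeps the raw IOT window tight (jitter-only SD), so
  # the 5-SD rule resolves a near-zero double-press interval unambiguously
  params <- breather_params(entrain_gain = 0, jitter_sd = 0.1,
                            intrinsic_ratio = 1)
  ev <- simulate_breather_events(params, duration = 480, seed = 31)
  k <- 3
  dup_idx <- c(30, 60, 90)
  dups <- tibble::tibble(time = ev$time[dup_idx] + 0.05,
                         kind = ev$kind[dup_idx])
  dirty <- dplyr::arrange(dplyr::bind_rows(ev, dups), time)
  iot <- cycle_metrics(dirty)$iot
  f <- outlier_filter(iot)
  expect_gte(sum(!attr(f, "keep")), k - 1)
  ts <- trial_series(dirty, "rate")
  expect_gt(skipped_fraction(ts), 0)
})
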