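test_that("pink noise is seed-deterministic with near-zero mean", {
  a <- generate_pink_noise(20000, seed = 7)
  b <- generate_pink_noise(20000, seed = 7)
  expect_identical(a$samples, b$samples)
  c <- generate_pink_noise(20000, seed = 8)
  expect_false(identical(a$samples, c$samples))

  # sample means of 1/f noise fluctuate far more than a white-noise CLT
  # bound suggests (the pinking filter has a large DC gain), but means of
  # independent renders are iid, so the CLT applies across seeds
  means <- vapply(1:20, function(s) mean(generate_pink_noise(20000, s)$samples),
                  0)
  expect_lt(abs(mean(means)), 4 * sd(means) / sqrt(length(means)))
})

test_that("pink noise falls at -10 dB/decade over the audio band", {
  x <- generate_pink_noise(2^20, seed = 1)$samples[, 1]
  psd <- breathsync:::welch_psd(x, 44100)
  band <- psd[psd$freq >= 20 & psd$freq <= 5000, ]
  fit <- lm(I(10 * log10(power)) ~ log10(freq), data = band)
  expect_equal(unname(coef(fit)[2]), -10, tolerance = 0.1)  # within +-1 dB
})

test_that("breath envelope gives 1:2 inhale:exhale with minima at onsets", {
  traj <- uniform_phase_traj(freq = 0.2, duration = 60)
  cfg <- stimulus_config()
  ctl <- breath_envelope(traj, cfg)
  ratio <- sum(ctl$region == "exhale") / sum(ctl$region == "inhale")
  expect_equal(ratio, 2, tolerance = 0.01)
  expect_true(all(ctl$amp >= 0 & ctl$amp <= 1))
  # amp at onset instants (phase ~0 and ~split) equals the trough
  onset_rows <- which(ctl$phase < 1e-6)
  expect_true(all(abs(ctl$amp[onset_rows] - cfg$amp_trough) < 1e-9))
  # exactly one local amp maximum per region per cycle
  one_cycle <- ctl[ctl$time < 5, ]
  for (reg in c("inhale", "exhale")) {
    a <- one_cycle$amp[one_cycle$region == reg]
    peaks <- sum(diff(sign(diff(a))) == -2)
    expect_equal(peaks, 1)
  }
})

test_that("envelope modulation is periodic at the breathing period", {
  traj <- uniform_phase_traj(freq = 0.2, duration = 120)
  ctl <- breath_envelope(traj)
  a <- ctl$amp - mean(ctl$amp)
  spec <- Mod(fft(a))^2
  freqs <- (seq_along(spec) - 1) * 100 / length(spec)
  peak <- freqs[which.max(spec[freqs > 0.01 & freqs < 5]) +
                  sum(freqs <= 0.01)]
  expect_equal(peak %% 0.2, 0, tolerance = 0.01)
  # autocorrelation confirms the fundamental period is the breath cycle
  lag_p <- 500  # 5 s at 100 Hz control rate
  ac <- function(lag) cor(a[1:(length(a) - lag)], a[(lag + 1):length(a)])
  expect_gt(ac(lag_p), 0.99)
  expect_lt(ac(round(lag_p / 2)), ac(lag_p))
})

test_that("noise renderer honours silence, passthrough and amplitude scaling", {
  traj <- uniform_phase_traj(freq = 0.2, duration = 4)
  cfg <- stimulus_config(sample_rate = 8000)
  ctl <- breath_envelope(traj, cfg)
  noise <- generate_pink_noise(8000 * 4, seed = 2, sample_rate = 8000)

  silent <- ctl; silent$amp <- 0
  out0 <- render_noise_stimulus(silent, noise, cfg)
  expect_true(all(out0$samples == 0))

  passthru <- ctl; passthru$amp <- 1; passthru$cutoff <- 4000  # Nyquist
  out1 <- render_noise_stimulus(passthru, noise, cfg)
  expect_equal(out1$samples[, 1], noise$samples[, 1], tolerance = 1e-12)
  expect_equal(out1$channels, 2)

  rms <- function(ctl_amp) {
    c2 <- ctl; c2$amp <- ctl$amp * ctl_amp
    sqrt(mean(render_noise_stimulus(c2, noise, cfg)$samples[, 1]^2))
  }
  levels <- vapply(c(0.2, 0.5, 1), rms, 0)
  expect_true(all(diff(levels) > 0))

  expect_error(render_noise_stimulus(ctl, generate_pink_noise(100, 2, 8000), cfg),
               class = "breathsync_synth_error")
})

test_that("music phrase spans two thirds of the period, scaling linearly", {
  for (period in c(4, 6, 10)) {
    notes <- compose_music_phrase(period)
    expect_equal(max(notes$onset + notes$duration), period * 2 / 3,
                 tolerance = 1e-12)
  }
  n1 <- compose_music_phrase(5)
  n2 <- compose_music_phrase(10)
  expect_equal(n2$onset, 2 * n1$onset)
  expect_equal(n2$duration, 2 * n1$duration)

  arp <- n1$pitch[n1$role == "arpeggio"]
  expect_true(all(diff(arp) < 0))
})

test_that("early-inhale fadeout ramps linearly from 1 to 0", {
  cfg <- stimulus_config(sample_rate = 1000, fade = 0.15)
  buf <- audio_buffer(rep(1, 1000), 1000)
  out <- apply_early_inhale_fadeout(buf, 0.4, cfg)
  at <- function(t) out$samples[round(t * 1000) + 1, 1]
  expect_equal(at(0.4), 1)
  expect_equal(at(0.4 + 0.15), 0, tolerance = 1e-9)
  expect_equal(at(0.4 + 0.075), 0.5, tolerance = 0.01)
  expect_true(all(out$samples[round(0.56 * 1000):1000, 1] == 0))
  expect_equal(at(0.2), 1)  # untouched before the inhale
})

test_that("nature radius breathes once per cycle within its bounds", {
  cfg <- stimulus_config()
  phi <- seq(0, 719, by = 1)
  r <- nature_radius(phi, cfg)
  expect_true(all(r >= cfg$r_min & r <= cfg$r_max))
  expect_equal(nature_radius(0, cfg), cfg$r_max)    # expands on inhale
  expect_equal(nature_radius(180, cfg), cfg$r_min)
  expect_equal(r[1:360], r[361:720])                # period = breath cycle
  expect_equal(nature_azimuths(), c(0, 45, 90, 135, 180, 225, 270, 315))
  inv <- stimulus_config(radius_expand_on = "exhale")
  expect_equal(nature_radius(180, inv), inv$r_max)
})

test_that("all stimulus families render deterministic, peak-safe stereo audio", {
  traj <- uniform_phase_traj(freq = 0.25, duration = 5)
  cfg <- stimulus_config(sample_rate = 8000)
  for (family in c("noise", "nature", "music")) {
    a <- render_stimulus(traj, family, cfg, seed = 5)
    b <- render_stimulus(traj, family, cfg, seed = 5)
    expect_identical(a$samples, b$samples)
    expect_equal(a$channels, 2)
    expect_lte(max(abs(a$samples)), 0.99)
    expect_gt(max(abs(a$samples)), 0)
  }
})

test_that("WAV files round-trip through write and read", {
  traj <- uniform_phase_traj(freq = 0.25, duration = 2)
  cfg <- stimulus_config(sample_rate = 8000)
  buf <- render_stimulus(traj, "noise", cfg, seed = 3)
  for (bits in c(16, 24)) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(buf, path, bits = bits)
    back <- read_wav(path)
    expect_equal(back$sample_rate, 8000)
    expect_equal(back$channels, 2)
    expect_lt(max(abs(back$samples - buf$samples)), 1.01 / (2^(bits - 1) - 1))
  }
  # byte-stable output for identical input
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(buf, p1); write_wav(buf, p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
})
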