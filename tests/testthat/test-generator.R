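test_that("generator config validation names the offending field", {
  expect_error(generator_config(sampling_rate = 900), "sampling_rate")
  expect_error(generator_config(duration = 10.0003), "duration")
  expect_error(generator_config(class_mix = c(0.5, 0.5, 0.5)), "class_mix")
  expect_error(generator_config(hfo_rate = -1), "hfo_rate")
  expect_error(generator_config(fr_freq_range = c(500, 250)),
               "fr_freq_range")
})

test_that("background is deterministic, scales to zero, and hits its RMS", {
  cfg <- generator_config(duration = 10, n_channels = 2, seed = 7)
  a <- generate_background(cfg, seed = 7)
  b <- generate_background(cfg, seed = 7)
  expect_identical(a$signal, b$signal)

  zero_cfg <- generator_config(duration = 2, background_rms = 0,
                               spike_rate = 0)
  z <- generate_background(zero_cfg)
  expect_true(all(z$signal == 0))

  cfg <- generator_config(duration = 60, n_channels = 2, spike_rate = 0,
                          seed = 3)
  rec <- generate_background(cfg)
  ch_rms <- sqrt(rowMeans(rec$signal^2))
  expect_true(all(abs(ch_rms - cfg$background_rms) <
                    0.1 * cfg$background_rms))
})

test_that("event sampling: rate, containment, non-overlap, class mix", {
  cfg <- generator_config(seed = 21)
  expect_identical(nrow(sample_events(generator_config(hfo_rate = 0,
                                                       duration = 10))), 0L)
  ann <- sample_events(cfg, seed = 21)
  # Poisson mean 4 channels x 5 min x 6 events/min = 120
  expect_lt(abs(nrow(ann) - 120), 3 * sqrt(120))
  expect_true(all(ann$start >= 0 & ann$end <= cfg$duration))
  expect_true(all(ann$end > ann$start))
  for (ch in unique(ann$channel_id)) {
    a <- ann[ann$channel_id == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1)
      expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  # class frequencies converge to class_mix (binomial 3-sigma bands)
  pool <- do.call(rbind, lapply(1:4, function(s)
    sample_events(generator_config(seed = s), seed = s)))
  p_r <- mean(pool$label == "R")
  expect_lt(abs(p_r - 0.90), 3 * sqrt(0.9 * 0.1 / nrow(pool)))
})

test_that("duration distributions match their configured means", {
  cfg <- generator_config()
  withr::with_seed(42, {
    r <- sample_durations(5000, cfg$ripple_duration)
    f <- sample_durations(5000, cfg$fr_duration)
  })
  expect_lt(abs(mean(r) - 96.2), 2.5)
  expect_lt(abs(mean(f) - 40.6), 1.5)
  expect_true(all(r >= 30 & r <= 300))
  expect_true(all(f >= 10 & f <= 150))
})

test_that("rendered events are in-band, zero-mean, and degenerate-safe", {
  fs <- 2000
  expect_true(all(render_event("R", 0.1, 150, 0, fs) == 0))
  expect_error(render_event("R", 0.01, 100, 1, fs), "degenerate-event")

  band_power <- function(x, lo, hi) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    keep <- f <= fs / 2
    sum(sp[keep & f >= lo & f <= hi]) / sum(sp[keep])
  }
  r <- render_event("R", 0.1, 150, 10, fs)
  expect_gt(band_power(r, 80, 250), 0.99)
  expect_lt(abs(mean(r)), 1e-2 * max(abs(r)))

  # FR containment: short events leak, so check at -20 dB as well as bulk
  fr <- render_event("FR", 0.04, 350, 10, fs)
  expect_gt(band_power(fr, 250, 500), 0.95)
  sp <- Mod(fft(fr))
  f <- (seq_along(fr) - 1) * fs / length(fr)
  keep <- f <= fs / 2
  out_peak <- max(sp[keep & (f < 250 | f > 500)])
  in_peak <- max(sp[keep & f >= 250 & f <= 500])
  expect_lt(20 * log10(out_peak / in_peak), -20)

  both <- render_event("FRonR", 0.1, c(150, 350), c(10, 10), fs)
  expect_gt(band_power(both, 80, 250), 0.2)
  expect_gt(band_power(both, 250, 500), 0.2)
})

test_that("generated recordings are reproducible with annotations intact", {
  cfg <- generator_config(duration = 10, n_channels = 2, seed = 9)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$annotations, b$annotations)
  expect_silent(hfopipe:::validate_annotations(a$annotations, a$recording))
})

test_that("a crude line-length threshold recovers very loud events", {
  gr <- small_subject(seed = 13, duration = 60, snr = 50)
  rec <- gr$recording
  ann <- gr$annotations
  expect_gt(nrow(ann), 0)
  fs <- rec$sampling_rate
  hits <- 0
  for (ch in unique(ann$channel_id)) {
    x <- bandpass_vector(rec$signal[ch, ], c(80, 500), fs)
    d <- abs(diff(x))
    # 99.9th percentile of the *background*: mask out annotated events
    bg <- rep(TRUE, length(d))
    a <- ann[ann$channel_id == ch, ]
    for (i in seq_len(nrow(a)))
      bg[(floor(a$start[i] * fs) + 1):ceiling(a$end[i] * fs)] <- FALSE
    thr <- quantile(d[bg], 0.999)
    for (i in seq_len(nrow(a))) {
      idx <- (floor(a$start[i] * fs) + 1):ceiling(a$end[i] * fs)
      if (any(d[idx] > thr)) hits <- hits + 1
    }
  }
  expect_gte(hits / nrow(ann), 0.95)
})
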