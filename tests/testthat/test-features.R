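# independent naive-loop oracles for the four energy features
oracle_line_length <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s / (length(x) - 1)
}
oracle_ste <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi^2
  s / length(x)
}
oracle_teager <- function(x) {
  s <- 0
  for (i in 2:(length(x) - 1)) s <- s + x[i]^2 - x[i - 1] * x[i + 1]
  s / (length(x) - 2)
}

test_that("energy features match worked examples exactly", {
  expect_equal(line_length(c(0, 1, 0, 1)), 1.0)
  expect_equal(line_length(rep(4.2, 10)), 0)
  expect_equal(short_time_energy(c(1, -1, 1, -1)), 1.0)
  expect_equal(short_time_energy(numeric(5)), 0)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2.5, 7)), 2.5)
  expect_equal(teager_energy(c(0, 1, 0)), 1)
  expect_equal(teager_energy(rep(3, 8)), 0)
})

test_that("features agree with naive-loop oracles on random windows", {
  withr::with_seed(101, {
    for (rep in 1:1000) {
      x <- rnorm(sample(3:50, 1), sd = 10^runif(1, -2, 2))
      expect_equal(line_length(x), oracle_line_length(x),
                   tolerance = 1e-9)
      expect_equal(short_time_energy(x), oracle_ste(x), tolerance = 1e-9)
      expect_equal(rms(x), sqrt(oracle_ste(x)), tolerance = 1e-9)
      expect_equal(teager_energy(x), oracle_teager(x), tolerance = 1e-9)
    }
  })
})

test_that("homogeneity and shift laws hold", {
  withr::with_seed(7, x <- rnorm(40))
  a <- -3.7
  expect_equal(line_length(a * x), abs(a) * line_length(x))
  expect_equal(rms(a * x), abs(a) * rms(x))
  expect_equal(short_time_energy(a * x), a^2 * short_time_energy(x))
  expect_equal(teager_energy(a * x), a^2 * teager_energy(x))
  # only line length is invariant under a constant shift
  expect_equal(line_length(x + 5), line_length(x))
})

test_that("Teager energy of a sinusoid equals A^2 sin^2(omega) per sample", {
  A <- 2.5; om <- 0.4; phi <- 1.1
  x <- A * sin(om * (1:100) + phi)
  expect_equal(teager_energy(x), A^2 * sin(om)^2, tolerance = 1e-10)
})

test_that("degenerate windows raise errors", {
  expect_error(line_length(1), "degenerate-window")
  expect_error(short_time_energy(numeric(0)), "degenerate-window")
  expect_error(rms(numeric(0)), "degenerate-window")
  expect_error(teager_energy(c(1, 2)), "degenerate-window")
})

test_that("band-pass filters pass in-band tones and reject out-of-band", {
  fs <- 2000
  t <- (0:19999) / fs
  x <- sin(2 * pi * 150 * t)
  mid <- 5000:15000
  g_in <- rms(bandpass_vector(x, c(80, 250), fs)[mid]) / rms(x[mid])
  g_out <- rms(bandpass_vector(x, c(250, 500), fs)[mid]) / rms(x[mid])
  expect_lt(abs(g_in - 1), 0.05)
  expect_lt(20 * log10(g_out), -40)
  expect_true(all(bandpass_vector(numeric(4000), c(80, 250), fs) == 0))
  rec <- recording(rbind(x, -x), fs)
  filt <- bandpass(rec, band_spec(80, 250))
  expect_equal(dim(filt$signal), dim(rec$signal))
  # channel independence: filtering commutes with channel order
  expect_equal(filt$signal[2, ], -filt$signal[1, ])
  expect_error(bandpass(rec, c(80, 1100)), "Nyquist")
})

test_that("segmentation produces the documented window grids", {
  s <- segment_indices(600000, 2000, 10)
  expect_identical(nrow(s), 30000L)
  expect_true(all(s$end_sample - s$start_sample == 20))
  expect_identical(nrow(segment_indices(600000, 2000, 100)), 3000L)
  expect_identical(nrow(segment_indices(19, 2000, 10)), 0L)
  # half-open, consecutive, non-overlapping
  expect_identical(s$start_sample[-1], s$end_sample[-nrow(s)])
})

test_that("segment labeling follows the overlap and precedence rules", {
  ann <- annotations("ch1", c(1.0), c(1.096), "R")
  expect_identical(label_segment(1.02, 1.03, ann), "R")
  ann_fr <- annotations("ch1", 0.106, 0.14, "FR")
  expect_identical(label_segment(0.10, 0.11, ann_fr), "noHFO")  # 0.4 < 0.5
  tie <- annotations(c("ch1", "ch1"), c(0.095, 0.105), c(0.105, 0.120),
                     c("R", "FRonR"))
  expect_identical(label_segment(0.10, 0.11, tie), "FRonR")

  # exhaustive small-case enumeration against a naive per-segment oracle
  oracle_label <- function(s, e, ann) {
    best <- "noHFO"; best_f <- 0
    prec <- c(noHFO = 0, R = 1, FR = 2, FRonR = 3)
    for (i in seq_len(nrow(ann))) {
      f <- max(0, min(e, ann$end[i]) - max(s, ann$start[i])) / (e - s)
      if (f > best_f || (f == best_f && prec[ann$label[i]] > prec[best])) {
        best_f <- f; best <- ann$label[i]
      }
    }
    if (best_f >= 0.5) best else "noHFO"
  }
  grid <- seq(0, 0.2, by = 0.01)
  labs <- c("R", "FR", "FRonR")
  withr::with_seed(11, {
    for (case in 1:200) {
      n_ev <- sample(1:3, 1)
      starts <- sort(sample(grid, n_ev))
      ends <- starts + sample(c(0.01, 0.025, 0.05), n_ev, replace = TRUE)
      ok <- logical(n_ev); max_end <- -Inf
      for (i in seq_len(n_ev)) {
        ok[i] <- starts[i] >= max_end
        if (ok[i]) max_end <- ends[i]
      }
      ann <- annotations(rep("ch1", sum(ok)), starts[ok], ends[ok],
                         sample(labs, sum(ok), replace = TRUE))
      s <- sample(grid, 1)
      expect_identical(label_segment(s, s + 0.01, ann),
                       oracle_label(s, s + 0.01, ann))
    }
  })
})

test_that("extract_features builds a consistent labeled table", {
  zero <- recording(matrix(0, 2, 4000), 2000, subject_id = "z")
  tz <- extract_features(zero, NULL, 10)
  expect_identical(nrow(tz), 2L * 200L)
  expect_true(all(as.matrix(tz[, hfopipe:::feature_columns()]) == 0))
  expect_true(all(tz$label == "noHFO"))

  gr <- small_subject(seed = 4, duration = 20, snr = 10)
  tbl <- extract_features(gr$recording, gr$annotations, 10)
  expect_identical(nrow(tbl), 2L * 2000L)
  expect_identical(names(tbl),
                   c(hfopipe:::PROVENANCE_COLUMNS,
                     hfopipe:::feature_columns(), "label"))
  # rms^2 equals short-time energy row-wise in every band
  for (b in c("band80_250", "band250_500", "band80_500"))
    expect_equal(tbl[[paste0(b, "_rms")]]^2,
                 tbl[[paste0(b, "_short_time_energy")]],
                 tolerance = 1e-9)
  expect_true(all(tbl$label %in%
                    c("noHFO", unique(gr$annotations$label))))
})

test_that("an FR event stands out in fast-ripple-band Teager energy", {
  cfg <- generator_config(duration = 20, n_channels = 1, event_snr = 10,
                          hfo_rate = 0, seed = 3)
  rec <- generate_background(cfg, seed = 3)
  ann <- annotations("ch1", 10.002, 10.042, "FR")
  w <- render_event("FR", 0.04, 350, 10 * sqrt(mean(
    bandpass_vector(rec$signal[1, ], c(250, 500), 2000)^2)), 2000)
  idx <- (floor(10.002 * 2000) + 1):(floor(10.002 * 2000) + length(w))
  rec$signal[1, idx] <- rec$signal[1, idx] + w
  tbl <- extract_features(rec, ann, 10)
  inside <- tbl$label == "FR"
  expect_gt(sum(inside), 0)
  noise_q99 <- quantile(tbl$band250_500_teager[!inside], 0.99)
  expect_true(all(tbl$band250_500_teager[inside] > noise_q99))
})
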