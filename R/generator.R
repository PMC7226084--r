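#' Generator configuration for synthetic annotated iEEG
#'
#' Defines the statistical structure the detection pipeline assumes:
#' 2000 Hz interictal recordings with 1/f^alpha background, occasional sharp
#' transients (interictal spikes, a classical source of false HFOs), and
#' injected oscillatory events in three classes — ripples (R, 80-250 Hz,
#' duration mean 96.2 sd 45.5 ms), fast ripples (FR, 250-500 Hz, mean 40.6
#' sd 26.7 ms) and fast ripples co-occurring with ripples (FRonR). Durations
#' are truncated normal; the parent location is calibrated so the truncated
#' distribution's mean equals the requested mean (naive truncation would
#' shift it upward by several ms). Default rates keep the fraction of 10 ms
#' segments overlapping an event below 10%, with ripples about 90% of events.
#'
#' @param sampling_rate Hz (must exceed twice the upper fast-ripple bound)
#' @param duration recording length in seconds
#' @param n_channels number of channels
#' @param background_exponent alpha of the 1/f^alpha background spectrum
#' @param background_rms broadband background RMS amplitude (signal units,
#'   conventionally microvolts)
#' @param spike_rate sharp-transient rate, events/min/channel (0 disables)
#' @param hfo_rate HFO event rate, events/min/channel
#' @param class_mix probabilities for classes R, FR, FRonR (named or in that
#'   order); must be non-negative and sum to 1
#' @param ripple_duration list(mean, sd, bounds) in ms for R (and FRonR)
#'   durations
#' @param fr_duration list(mean, sd, bounds) in ms for FR durations
#' @param ripple_freq_range,fr_freq_range frequency ranges (Hz) events are
#'   drawn from
#' @param event_snr peak in-band event amplitude relative to the in-band
#'   background RMS
#' @param spike_amplitude sharp-transient peak relative to broadband
#'   background RMS
#' @param seed integer seed; fully determines `generate_recording()` output
#' @return a validated `generator_config` list
#' @export
generator_config <- function(sampling_rate = 2000, duration = 300,
                             n_channels = 4, background_exponent = 1.0,
                             background_rms = 25, spike_rate = 1.0,
                             hfo_rate = 6.0,
                             class_mix = c(R = 0.90, FR = 0.05, FRonR = 0.05),
                             ripple_duration = list(mean = 96.2, sd = 45.5,
                                                    bounds = c(30, 300)),
                             fr_duration = list(mean = 40.6, sd = 26.7,
                                                bounds = c(10, 150)),
                             ripple_freq_range = c(80, 250),
                             fr_freq_range = c(250, 500),
                             event_snr = 3.0, spike_amplitude = 5.0,
                             seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              n_channels = n_channels,
              background_exponent = background_exponent,
              background_rms = background_rms, spike_rate = spike_rate,
              hfo_rate = hfo_rate, class_mix = class_mix,
              ripple_duration = ripple_duration, fr_duration = fr_duration,
              ripple_freq_range = ripple_freq_range,
              fr_freq_range = fr_freq_range, event_snr = event_snr,
              spike_amplitude = spike_amplitude, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#' @param cfg a `generator_config`
#' @return the config, invisibly-checked; errors name the offending field
#' @export
validate_generator_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid generator config field '", field, "': ", msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$sampling_rate) && cfg$sampling_rate > 0, "sampling_rate",
      "must be a positive number")
  chk(cfg$sampling_rate > 2 * max(cfg$fr_freq_range), "sampling_rate",
      "must exceed twice the upper fast-ripple frequency bound (Nyquist)")
  chk(num1(cfg$duration) && cfg$duration > 0, "duration", "must be > 0")
  ns <- cfg$duration * cfg$sampling_rate
  chk(abs(ns - round(ns)) < 1e-9, "duration",
      "duration * sampling_rate must be an integer sample count")
  chk(num1(cfg$n_channels) && cfg$n_channels >= 1 &&
        cfg$n_channels == round(cfg$n_channels), "n_channels",
      "must be a positive integer")
  chk(num1(cfg$background_rms) && cfg$background_rms >= 0, "background_rms",
      "must be >= 0")
  chk(num1(cfg$background_exponent) && cfg$background_exponent >= 0,
      "background_exponent", "must be >= 0")
  chk(num1(cfg$spike_rate) && cfg$spike_rate >= 0, "spike_rate",
      "must be >= 0")
  chk(num1(cfg$hfo_rate) && cfg$hfo_rate >= 0, "hfo_rate", "must be >= 0")
  mix <- cfg$class_mix
  chk(is.numeric(mix) && length(mix) == 3 && all(mix >= 0) &&
        abs(sum(mix) - 1) < 1e-9, "class_mix",
      "must be 3 non-negative probabilities summing to 1")
  for (fld in c("ripple_duration", "fr_duration")) {
    d <- cfg[[fld]]
    chk(is.list(d) && num1(d$mean) && num1(d$sd) && d$sd > 0 &&
          length(d$bounds) == 2 && d$bounds[1] > 0 &&
          d$bounds[1] < d$mean && d$mean < d$bounds[2], fld,
        "needs positive mean within bounds and sd > 0")
  }
  for (fld in c("ripple_freq_range", "fr_freq_range")) {
    fr <- cfg[[fld]]
    chk(is.numeric(fr) && length(fr) == 2 && 0 < fr[1] && fr[1] < fr[2],
        fld, "must be an increasing positive pair of frequencies")
  }
  chk(num1(cfg$event_snr) && cfg$event_snr >= 0, "event_snr", "must be >= 0")
  chk(num1(cfg$seed) && cfg$seed >= 0, "seed",
      "must be a non-negative integer")
  cfg
}

# mean of a normal(mu, sd) truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- pnorm(be) - pnorm(al)
  mu + sd * (dnorm(al) - dnorm(be)) / Z
}

# parent location such that the [a, b]-truncated normal has the target mean
calibrate_truncnorm_location <- function(target_mean, sd, a, b) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, a, b) - target_mean,
                 lower = a, upper = b, extendInt = "yes",
                 tol = 1e-10)$root
}

#' Draw durations from a mean-calibrated truncated normal
#'
#' Samples from normal(location, sd) truncated to `bounds`, with the
#' location calibrated so that the truncated mean equals `spec$mean`.
#' Inverse-CDF sampling, so draws consume exactly `n` uniforms.
#'
#' @param n number of draws
#' @param spec list(mean, sd, bounds) as stored in a `generator_config`
#' @return numeric vector of durations (same units as `spec`)
#' @export
sample_durations <- function(n, spec) {
  if (n == 0) return(numeric())
  a <- spec$bounds[1]; b <- spec$bounds[2]
  mu <- calibrate_truncnorm_location(spec$mean, spec$sd, a, b)
  u <- runif(n, pnorm(a, mu, spec$sd), pnorm(b, mu, spec$sd))
  qnorm(u, mu, spec$sd)
}

# Gaussian 1/f^alpha noise of length n with unit RMS, via spectral shaping.
# The symmetric amplitude profile preserves Hermitian symmetry so the
# inverse transform is real.
one_over_f_noise <- function(n, alpha, fs) {
  white <- rnorm(n)
  if (alpha == 0) return(white / sqrt(mean(white^2)))
  spec <- fft(white)
  k <- 0:(n - 1)
  kfold <- pmin(k, n - k)            # two-sided frequency index
  f <- kfold * fs / n
  amp <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(fft(spec * amp, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Draw an event's center frequency uniformly inside its nominal band,
# keeping a margin from the band edges so the rendered tone's spectral
# support (main lobe width ~ 2/duration, plus the analysis filters'
# transition width) stays inside the band: events are in-band by
# construction, not only up to leakage.
sample_event_freq <- function(range, duration) {
  margin <- max(10, 2 / duration)
  lo <- range[1] + margin
  hi <- range[2] - margin
  if (lo >= hi) return(mean(range))
  runif(1, lo, hi)
}

# biphasic sharp transient (one tapered sine cycle), unit peak amplitude
spike_waveform <- function(duration_s, fs) {
  nsamp <- max(4L, round(duration_s * fs))
  t <- seq_len(nsamp) - 1
  w <- sin(2 * pi * t / (nsamp - 1)) * hann_window(nsamp)
  w / max(abs(w))
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Tukey (tapered-cosine) window: flat at 1 except cosine ramps covering
# `taper`/2 of the support at each end. taper = 1 gives a Hann window,
# taper = 0 a rectangular one.
tukey_window <- function(n, taper = 0.1) {
  if (n == 1) return(1)
  if (taper <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < taper / 2
  hi <- t > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / taper - 1)))
  w
}

#' Generate background iEEG (no HFO events)
#'
#' Produces `n_channels` of 1/f^alpha noise scaled to `background_rms`, with
#' biphasic sharp transients (20-70 ms interictal spikes) superimposed at
#' `spike_rate`. Identical `(config, seed)` gives bit-identical output.
#'
#' @param config a `generator_config`
#' @param seed integer seed (defaults to `config$seed`)
#' @return an `hfo_recording`
#' @export
generate_background <- function(config, seed = config$seed) {
  config <- validate_generator_config(config)
  fs <- config$sampling_rate
  nsamp <- round(config$duration * fs)
  with_seed(seed, {
    sig <- matrix(0, nrow = config$n_channels, ncol = nsamp)
    for (ch in seq_len(config$n_channels)) {
      if (config$background_rms > 0) {
        x <- one_over_f_noise(nsamp, config$background_exponent, fs) *
          config$background_rms
        n_spikes <- rpois(1, config$spike_rate * config$duration / 60)
        if (n_spikes > 0) {
          for (s in seq_len(n_spikes)) {
            dur <- runif(1, 0.020, 0.070)
            w <- spike_waveform(dur, fs) * config$spike_amplitude *
              config$background_rms
            start <- floor(runif(1, 0, nsamp - length(w))) + 1
            idx <- start:(start + length(w) - 1)
            x[idx] <- x[idx] + w
          }
        }
        sig[ch, ] <- x
      }
    }
    recording(sig, fs, subject_id = sprintf("sim%03d", seed %% 1000L))
  })
}

#' Sample ground-truth HFO event annotations
#'
#' Per channel, event onsets follow a homogeneous Poisson process at
#' `hfo_rate` events/min; each event's class is drawn from `class_mix` and
#' its duration from the class's truncated-normal distribution (FRonR uses
#' the ripple duration: it is one composite event, a ripple hosting a fast
#' ripple). Events that would overlap an already-placed event on the same
#' channel are rejected and redrawn; all events lie strictly inside the
#' recording.
#'
#' @param config a `generator_config`
#' @param seed integer seed (defaults to `config$seed`)
#' @return an `hfo_annotations` data.frame sorted by channel and start time
#' @export
sample_events <- function(config, seed = config$seed) {
  config <- validate_generator_config(config)
  T <- config$duration
  with_seed(seed, {
    rows <- list()
    for (ch in seq_len(config$n_channels)) {
      ch_id <- paste0("ch", ch)
      n_ev <- rpois(1, config$hfo_rate * T / 60)
      if (n_ev == 0) next
      placed_start <- numeric(0); placed_end <- numeric(0)
      for (ev in seq_len(n_ev)) {
        cls <- sample(HFO_LABELS, 1, prob = config$class_mix)
        dspec <- if (cls == "FR") config$fr_duration else
          config$ripple_duration
        dur <- sample_durations(1, dspec) / 1000
        fails <- 0
        repeat {
          start <- runif(1, 0, T - dur)
          end <- start + dur
          if (!any(start < placed_end & end > placed_start)) break
          fails <- fails + 1
          if (fails >= 1000)
            stop("infeasible-rate error: could not place event without ",
                 "overlap after 1000 attempts (hfo_rate too high)")
        }
        placed_start <- c(placed_start, start)
        placed_end <- c(placed_end, end)
        rows[[length(rows) + 1]] <- data.frame(
          channel_id = ch_id, start = start, end = start + dur,
          label = cls, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(annotations())
    ann <- do.call(rbind, rows)
    ann <- ann[order(ann$channel_id, ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    class(ann) <- c("hfo_annotations", "data.frame")
    ann
  })
}

#' Render a single HFO waveform
#'
#' Ripples and fast ripples are windowed sinusoids under a tapered-cosine
#' (Tukey) envelope: near-full amplitude over the annotated extent with
#' brief cosine ramps (`edge_taper`/2 of the duration at each end), because
#' ground-truth marks delimit where the oscillation is visible — an
#' envelope that decays over most of the marked interval would make the
#' annotation mislabel its own edges. An FRonR event is the sum of a ripple
#' waveform and a fast-ripple waveform whose support is contained in the
#' ripple support (centred, `fr_fraction` of the duration). The windowed
#' oscillation integrates to approximately zero.
#'
#' @param event_class one of `"R"`, `"FR"`, `"FRonR"`
#' @param duration event duration in seconds
#' @param center_freqs sinusoid frequency in Hz; for FRonR a length-2 vector
#'   (ripple component, fast-ripple component)
#' @param amplitude peak amplitude; for FRonR a length-2 vector matching
#'   `center_freqs`
#' @param fs sampling rate in Hz
#' @param phase initial phase(s), radians
#' @param fr_fraction for FRonR, fraction of the ripple support occupied by
#'   the embedded fast ripple. The default keeps fast-ripple content under
#'   nearly the whole annotated extent: a mark labeled FRonR asserts
#'   co-occurrence over the marked interval, and fixed-window segments cut
#'   from it should carry both bands' signatures
#' @param edge_taper total taper fraction of the Tukey envelope (0.1 =
#'   5% cosine ramp at each edge; 1 gives a Hann envelope)
#' @return numeric waveform of `round(duration * fs)` samples
#' @export
render_event <- function(event_class, duration, center_freqs, amplitude,
                         fs, phase = 0, fr_fraction = 1,
                         edge_taper = 0.1) {
  event_class <- match.arg(event_class, HFO_LABELS)
  nsamp <- round(duration * fs)
  f_low <- min(center_freqs)
  if (duration < 2 / f_low)
    stop("degenerate-event error: duration ", signif(duration, 3),
         " s is below 2 cycles of ", f_low, " Hz")
  osc <- function(n, f, a, ph) {
    t <- (0:(n - 1)) / fs
    a * sin(2 * pi * f * t + ph) * tukey_window(n, edge_taper)
  }
  phase <- rep_len(phase, 2)
  if (event_class %in% c("R", "FR"))
    return(osc(nsamp, center_freqs[1], amplitude[1], phase[1]))
  # FRonR: ripple carrier plus an embedded, centred fast ripple
  stopifnot(length(center_freqs) >= 2, length(amplitude) >= 2)
  w <- osc(nsamp, center_freqs[1], amplitude[1], phase[1])
  n_fr <- max(4L, round(fr_fraction * nsamp))
  off <- floor((nsamp - n_fr) / 2)
  w[(off + 1):(off + n_fr)] <- w[(off + 1):(off + n_fr)] +
    osc(n_fr, center_freqs[2], amplitude[2], phase[2])
  w
}

#' Generate a complete annotated synthetic recording
#'
#' Background plus rendered events at the annotated positions. Each event's
#' peak in-band amplitude is `event_snr` times the background RMS inside its
#' own frequency band (ripple band for the R component, fast-ripple band for
#' the FR component), measured on the band-filtered background of the same
#' channel.
#'
#' @param config a `generator_config`; `config$seed` drives all randomness
#' @return a list with elements `recording` (an `hfo_recording`) and
#'   `annotations` (an `hfo_annotations` data.frame)
#' @export
generate_recording <- function(config) {
  config <- validate_generator_config(config)
  seeds <- derive_seeds(config$seed, 3)
  rec <- generate_background(config, seeds[1])
  ann <- sample_events(config, seeds[2])
  fs <- config$sampling_rate
  if (nrow(ann) > 0 && config$event_snr > 0 && config$background_rms > 0) {
    # per-channel in-band background RMS, the SNR reference
    r_rms <- f_rms <- setNames(numeric(nrow(rec$signal)), rec$channel_ids)
    for (ch in rec$channel_ids) {
      x <- rec$signal[ch, ]
      r_rms[ch] <- sqrt(mean(bandpass_vector(x, config$ripple_freq_range, fs)^2))
      f_rms[ch] <- sqrt(mean(bandpass_vector(x, config$fr_freq_range, fs)^2))
    }
    with_seed(seeds[3], {
      for (i in seq_len(nrow(ann))) {
        ch <- ann$channel_id[i]
        dur <- ann$end[i] - ann$start[i]
        cls <- ann$label[i]
        f_r <- sample_event_freq(config$ripple_freq_range, dur)
        f_f <- sample_event_freq(config$fr_freq_range, dur)
        ph <- runif(2, 0, 2 * pi)
        w <- switch(cls,
          R = render_event("R", dur, f_r, config$event_snr * r_rms[ch],
                           fs, ph[1]),
          FR = render_event("FR", dur, f_f, config$event_snr * f_rms[ch],
                            fs, ph[1]),
          FRonR = render_event("FRonR", dur, c(f_r, f_f),
                               config$event_snr * c(r_rms[ch], f_rms[ch]),
                               fs, ph))
        start <- floor(ann$start[i] * fs) + 1
        idx <- start:(start + length(w) - 1)
        idx <- idx[idx <= ncol(rec$signal)]
        rec$signal[ch, idx] <- rec$signal[ch, idx] + w[seq_along(idx)]
      }
    })
  }
  list(recording = rec, annotations = ann)
}
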