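#' Band specification
#'
#' The analysis uses three fixed bands: the ripple band (80-250 Hz), the
#' fast-ripple band (250-500 Hz) and the overall HFO band (80-500 Hz).
#'
#' @param low,high band edges in Hz
#' @param name optional band name
#' @return a `band_spec` list
#' @export
band_spec <- function(low, high, name = sprintf("band%g_%g", low, high)) {
  if (!(0 < low && low < high))
    stop("band edges must satisfy 0 < low < high")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' The three standard HFO analysis bands
#' @return named list of `band_spec`s: ripple (80-250), fast ripple
#'   (250-500), overall (80-500)
#' @export
standard_bands <- function() {
  lapply(names(BAND_SET), function(nm)
    band_spec(BAND_SET[[nm]][1], BAND_SET[[nm]][2], nm))
}

# Linear-phase FIR band-pass coefficients (Hamming-window design).
# Order is chosen so the one-pass transition band is ~20 Hz at fs = 2000 Hz;
# the filter is applied forward-backward, which squares the magnitude
# response (stop-band attenuation doubles in dB, pass-band stays flat).
fir_coefficients <- function(low, high, fs, order = NULL) {
  nyq <- fs / 2
  if (!(0 < low && low < high && high <= nyq))
    stop("configuration error: band [", low, ", ", high,
         "] Hz violates Nyquist for fs = ", fs, " Hz")
  if (is.null(order)) {
    trans <- 20                       # Hz, per-edge transition width
    order <- ceiling(3.3 * fs / trans / 2) * 2   # Hamming rule, even order
  }
  w <- c(low, high) / nyq
  type <- if (high >= nyq * 0.999) "high" else "pass"
  if (type == "high") signal::fir1(order, w[1], type = "high")
  else signal::fir1(order, w, type = "pass")
}

# Zero-phase application of a linear-phase FIR via the frequency domain:
# multiply the spectrum by |H(f)|^2, the exact circular equivalent of
# forward-backward filtering. Wrap-around affects only ~order samples at
# the record edges, negligible for multi-second recordings.
zero_phase_apply <- function(x, h) {
  n <- length(x)
  H <- fft(c(h, rep(0, n - length(h))))
  Re(fft(fft(x) * (Mod(H)^2), inverse = TRUE)) / n
}

#' Zero-phase band-pass filter a single channel
#' @param x numeric vector
#' @param band length-2 numeric `c(low, high)` in Hz or a `band_spec`
#' @param fs sampling rate in Hz
#' @return filtered vector, same length
#' @export
bandpass_vector <- function(x, band, fs) {
  if (inherits(band, "band_spec")) band <- c(band$low, band$high)
  h <- fir_coefficients(band[1], band[2], fs)
  zero_phase_apply(x, h)
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a linear-phase FIR band-pass forward-backward to every channel,
#' so band-filtered events keep their annotated timing. One-pass design
#' targets < 1 dB pass-band ripple and >= 40 dB stop-band attenuation 20 Hz
#' outside the band edges; the two-pass application exceeds both.
#'
#' @param rec an `hfo_recording`
#' @param band a `band_spec` or `c(low, high)` in Hz
#' @return a new `hfo_recording` with filtered signal
#' @export
bandpass <- function(rec, band) {
  if (inherits(band, "band_spec")) band <- c(band$low, band$high)
  h <- fir_coefficients(band[1], band[2], rec$sampling_rate)
  out <- rec
  for (ch in seq_len(nrow(rec$signal)))
    out$signal[ch, ] <- zero_phase_apply(rec$signal[ch, ], h)
  out
}

#' Fixed-window segment indices
#'
#' Consecutive non-overlapping half-open sample windows
#' `[start, start + w)`; a trailing partial window is dropped.
#'
#' @param n_samples samples available
#' @param fs sampling rate Hz
#' @param window_ms window length in ms; `window_ms * fs / 1000` must be an
#'   integer
#' @return data.frame with 1-based `start_sample` and exclusive `end_sample`
#' @export
segment_indices <- function(n_samples, fs, window_ms) {
  w <- window_ms * fs / 1000
  if (abs(w - round(w)) > 1e-9)
    stop("window length ", window_ms, " ms is not an integer number of ",
         "samples at ", fs, " Hz")
  w <- as.integer(round(w))
  n_win <- n_samples %/% w
  if (n_win == 0)
    return(data.frame(start_sample = integer(), end_sample = integer()))
  starts <- (seq_len(n_win) - 1L) * w + 1L
  data.frame(start_sample = starts, end_sample = starts + w)
}

#' Label one segment from ground-truth annotations
#'
#' The segment takes the class of the event with which its temporal overlap
#' fraction (overlap / window length) is maximal, provided that fraction is
#' at least 0.5; otherwise `noHFO`. Ties are broken by the precedence
#' FRonR > FR > R (the rarer, more specific class wins).
#'
#' @param start_s,end_s segment bounds in seconds (half-open)
#' @param ann annotations for the segment's channel
#' @return one of `"noHFO"`, `"R"`, `"FR"`, `"FRonR"`
#' @export
label_segment <- function(start_s, end_s, ann) {
  label_segments(start_s, end_s, ann)
}

#' Vectorised segment labeling
#' @param start_s,end_s vectors of segment bounds in seconds
#' @param ann annotations for the channel (data.frame with start/end/label)
#' @return character vector of labels
#' @export
label_segments <- function(start_s, end_s, ann) {
  n <- length(start_s)
  out <- rep("noHFO", n)
  if (is.null(ann) || nrow(ann) == 0) return(out)
  wlen <- end_s - start_s
  prec <- c(R = 1, FR = 2, FRonR = 3)
  best_frac <- numeric(n)
  best_prec <- numeric(n)
  for (i in seq_len(nrow(ann))) {
    ov <- pmax(0, pmin(end_s, ann$end[i]) - pmax(start_s, ann$start[i]))
    frac <- ov / wlen
    p <- prec[[ann$label[i]]]
    take <- frac > best_frac | (frac == best_frac & frac > 0 & p > best_prec)
    best_prec[take] <- p
    best_frac[take] <- frac[take]
    out[take & frac >= 0.5] <- ann$label[i]
  }
  out[best_frac < 0.5] <- "noHFO"
  out
}

#' Line length of a windowed signal
#'
#' Mean absolute first difference, `(1/(N-1)) * sum |x[n+1] - x[n]|`: an
#' amplitude-and-frequency-sensitive energy surrogate.
#'
#' @param x numeric vector, length >= 2
#' @return non-negative scalar
#' @export
line_length <- function(x) {
  if (length(x) < 2) stop("degenerate-window error: line_length needs N >= 2")
  mean(abs(diff(x)))
}

#' Short-time energy of a windowed signal
#'
#' Mean squared amplitude, `(1/N) * sum x[n]^2`.
#'
#' @param x numeric vector, length >= 1
#' @return non-negative scalar
#' @export
short_time_energy <- function(x) {
  if (length(x) < 1) stop("degenerate-window error: empty window")
  mean(x^2)
}

#' Root mean square of a windowed signal
#' @param x numeric vector, length >= 1
#' @return non-negative scalar; `rms(x)^2 == short_time_energy(x)`
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("degenerate-window error: empty window")
  sqrt(mean(x^2))
}

#' Mean Teager energy of a windowed signal
#'
#' `(1/(N-2)) * sum_{n=2}^{N-1} (x[n]^2 - x[n-1] x[n+1])`. For a sinusoid
#' `A sin(w n)` every term equals `A^2 sin^2(w)`, i.e. the operator tracks
#' instantaneous amplitude times frequency.
#'
#' @param x numeric vector, length >= 3
#' @return scalar (can be negative for non-sinusoidal input)
#' @export
teager_energy <- function(x) {
  n <- length(x)
  if (n < 3) stop("degenerate-window error: teager_energy needs N >= 3")
  mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
}

# all four features for every column of a (window_length x n_windows) matrix
window_features_matrix <- function(M) {
  N <- nrow(M)
  ll <- colSums(abs(M[-1, , drop = FALSE] - M[-N, , drop = FALSE])) / (N - 1)
  ste <- colMeans(M^2)
  tg <- colSums(M[2:(N - 1), , drop = FALSE]^2 -
                  M[1:(N - 2), , drop = FALSE] * M[3:N, , drop = FALSE]) /
    (N - 2)
  cbind(line_length = ll, short_time_energy = ste, rms = sqrt(ste),
        teager = tg)
}

#' Extract the 12-feature segment table from a recording
#'
#' Filters the recording once per band (ripple 80-250 Hz, fast ripple
#' 250-500 Hz, overall 80-500 Hz), cuts every band-filtered channel into
#' identical fixed windows, computes line length, short-time energy, RMS and
#' Teager energy per band (12 columns, band-major), and labels each segment
#' from the unfiltered time axis using the >= 50% overlap rule.
#'
#' @param rec an `hfo_recording`
#' @param ann an `hfo_annotations` data.frame (may be empty / NULL)
#' @param window_ms window length in ms (10, 50 or 100 in the study design;
#'   any integer-sample length is accepted)
#' @return a `segment_feature_table` data.frame: 5 provenance columns
#'   (subject_id, channel_id, segment_start, window_ms, synthetic), the 12
#'   features, and `label`
#' @export
extract_features <- function(rec, ann = NULL, window_ms = 10) {
  if (!inherits(rec, "hfo_recording")) stop("rec must be an hfo_recording")
  if (!is.null(ann) && nrow(ann) > 0) validate_annotations(ann, rec)
  fs <- rec$sampling_rate
  seg <- segment_indices(ncol(rec$signal), fs, window_ms)
  n_win <- nrow(seg)
  if (n_win == 0) stop("recording shorter than one window")
  wlen <- seg$end_sample[1] - seg$start_sample[1]
  bands <- standard_bands()
  hs <- lapply(bands, function(b) fir_coefficients(b$low, b$high, fs))
  rows <- vector("list", length(rec$channel_ids))
  for (ci in seq_along(rec$channel_ids)) {
    ch <- rec$channel_ids[ci]
    x <- rec$signal[ci, ]
    feats <- matrix(NA_real_, nrow = n_win, ncol = 12)
    for (bi in seq_along(bands)) {
      xf <- zero_phase_apply(x, hs[[bi]])
      M <- matrix(xf[1:(n_win * wlen)], nrow = wlen)
      feats[, (bi - 1) * 4 + (1:4)] <- window_features_matrix(M)
    }
    colnames(feats) <- feature_columns()
    ch_ann <- if (is.null(ann) || nrow(ann) == 0) NULL else
      ann[ann$channel_id == ch, , drop = FALSE]
    start_s <- (seg$start_sample - 1) / fs
    end_s <- (seg$end_sample - 1) / fs
    labels <- label_segments(start_s, end_s, ch_ann)
    rows[[ci]] <- data.frame(
      subject_id = rec$subject_id, channel_id = ch,
      segment_start = start_s, window_ms = window_ms, synthetic = FALSE,
      feats, label = labels, stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("segment_feature_table", "data.frame")
  tbl
}
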