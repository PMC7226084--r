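# Shared fixtures, built in code at test time.

# Minimal segment-feature-table skeleton around a given feature matrix.
as_feature_table <- function(X, labels, subject = "s1", window_ms = 10) {
  X <- as.matrix(X)
  colnames(X) <- hfopipe:::feature_columns()
  tbl <- data.frame(subject_id = subject, channel_id = "ch1",
                    segment_start = (seq_len(nrow(X)) - 1) * window_ms / 1000,
                    window_ms = window_ms, synthetic = FALSE,
                    X, label = labels, stringsAsFactors = FALSE)
  class(tbl) <- c("segment_feature_table", "data.frame")
  tbl
}

# Gaussian clouds in 12-d feature space, one per requested class label.
# `sep` controls cloud separation in units of the within-cloud sd.
cloud_table <- function(n_per_class, sep = 6, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(names(n_per_class), n_per_class)
    centers <- matrix(0, length(n_per_class), 12)
    for (i in seq_along(n_per_class))
      centers[i, ] <- rnorm(12) * sep
    X <- t(vapply(match(labels, names(n_per_class)),
                  function(ci) centers[ci, ] + rnorm(12, sd = sd),
                  numeric(12)))
    as_feature_table(X, labels)
  })
}

# Small annotated synthetic subject used by several suites.
small_subject <- function(seed = 5, duration = 30, snr = 3,
                          n_channels = 2) {
  cfg <- generator_config(duration = duration, n_channels = n_channels,
                          event_snr = snr, seed = seed)
  generate_recording(cfg)
}
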