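#' Construct a multichannel recording
#'
#' The raw substrate of every pipeline stage: a channels x samples matrix of
#' signal values (conventionally microvolts) with its sampling rate and
#' channel identifiers.
#'
#' @param signal numeric matrix, channels in rows, samples in columns
#' @param sampling_rate sampling frequency in Hz (> 0)
#' @param channel_ids character vector, one unique id per row of `signal`
#' @param subject_id subject identifier string
#' @return an object of class `hfo_recording`
#' @export
recording <- function(signal, sampling_rate, channel_ids = NULL,
                      subject_id = "subject") {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric channels x samples matrix")
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(signal)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(signal))
    stop("channel_ids length (", length(channel_ids),
         ") must equal the number of signal rows (", nrow(signal), ")")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  rownames(signal) <- channel_ids
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_ids = channel_ids, subject_id = as.character(subject_id)),
    class = "hfo_recording")
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf("<hfo_recording> subject '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  invisible(x)
}

#' Number of samples per channel
#' @param rec an `hfo_recording`
#' @return integer sample count
#' @export
n_samples <- function(rec) ncol(rec$signal)

#' Construct an event annotation table
#'
#' One row per ground-truth event: the channel it occurs on, start and end
#' times in seconds (half-open interval `[start, end)`), and the event class.
#'
#' @param channel_id character vector of channel ids
#' @param start,end event bounds in seconds; `end > start` required
#' @param label event class, one of `"R"`, `"FR"`, `"FRonR"`
#' @return a data.frame with class `hfo_annotations`
#' @export
annotations <- function(channel_id = character(), start = numeric(),
                        end = numeric(), label = character()) {
  ann <- data.frame(channel_id = as.character(channel_id),
                    start = as.numeric(start), end = as.numeric(end),
                    label = as.character(label), stringsAsFactors = FALSE)
  validate_annotations(ann)
  class(ann) <- c("hfo_annotations", "data.frame")
  ann
}

validate_annotations <- function(ann, recording = NULL) {
  stopifnot(all(c("channel_id", "start", "end", "label") %in% names(ann)))
  bad <- which(!ann$label %in% HFO_LABELS)
  if (length(bad))
    stop("unknown annotation label(s): ",
         paste(unique(ann$label[bad]), collapse = ", "),
         " (allowed: ", paste(HFO_LABELS, collapse = ", "), ")")
  bad <- which(!(ann$end > ann$start))
  if (length(bad))
    stop("annotation rows with end <= start: ",
         paste(bad, collapse = ", "))
  if (!is.null(recording)) {
    missing <- setdiff(unique(ann$channel_id), recording$channel_ids)
    if (length(missing))
      stop("annotation channel(s) absent from recording: ",
           paste(missing, collapse = ", "))
  }
  invisible(ann)
}
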