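# --- recordings ------------------------------------------------------------

# The package supports two on-disk signal formats:
#  * "container": plain CSV (one column per channel, one row per sample)
#    with a JSON sidecar (<stem>.json) carrying sampling_rate, channel_ids,
#    subject_id. Lossless to printed precision; the primary format.
#  * "edf": a minimal European Data Format writer/reader (single sampling
#    rate, 1-second data records, 16-bit samples with physical/digital
#    scaling). Round-trip is exact to the 16-bit container precision.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Write a recording to disk
#'
#' @param rec an `hfo_recording`
#' @param path output path; extension `.csv` (container) or `.edf`
#' @param format `"container"` or `"edf"`; default inferred from extension
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||%
    switch(tolower(tools::file_ext(path)), edf = "edf", "container")
  if (format == "edf") return(write_edf(rec, path))
  dt <- data.table::as.data.table(t(rec$signal))
  data.table::setnames(dt, rec$channel_ids)
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, channel_ids = rec$channel_ids,
         subject_id = rec$subject_id, n_samples = ncol(rec$signal)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path `.csv` container (with its `.json` sidecar) or `.edf` file
#' @param format_hint optional `"container"` or `"edf"`; default inferred
#'   from the extension
#' @return an `hfo_recording` with the sampling rate taken from file
#'   metadata; EDF files whose channels have different sampling rates are
#'   rejected
#' @export
read_recording <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  format <- format_hint %||%
    switch(tolower(tools::file_ext(path)), edf = "edf", "container")
  if (format == "edf") return(read_edf(path))
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("format error: missing sidecar metadata file ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dt <- data.table::fread(path)
  sig <- t(as.matrix(dt))
  if (!is.null(meta$n_samples) && ncol(sig) != meta$n_samples)
    stop("format error: ", path, " has ", ncol(sig),
         " samples/channel but sidecar declares ", meta$n_samples)
  recording(sig, as.numeric(meta$sampling_rate),
            as.character(meta$channel_ids),
            meta$subject_id %||% "subject")
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  nsamp <- ncol(rec$signal)
  if (nsamp %% fs != 0)
    stop("EDF writer requires a whole number of 1-second records")
  n_rec <- nsamp %/% fs
  ns <- nrow(rec$signal)
  phys_max <- apply(abs(rec$signal), 1, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767; dig_min <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii(rec$subject_id, 80),
    pad_ascii("hfopipe", 80), pad_ascii("01.01.00", 8),
    pad_ascii("00.00.00", 8), pad_ascii(256 * (1 + ns), 8),
    pad_ascii("", 44), pad_ascii(n_rec, 8), pad_ascii(1, 8),
    pad_ascii(ns, 4))
  sig_hdr <- paste0(
    paste(pad_ascii(rec$channel_ids, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste(pad_ascii(sprintf("%.6g", -phys_max), 8), collapse = ""),
    paste(pad_ascii(sprintf("%.6g", phys_max), 8), collapse = ""),
    paste(rep(pad_ascii(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_ascii(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 80), ns), collapse = ""),
    paste(rep(pad_ascii(fs, 8), ns), collapse = ""),
    paste(rep(pad_ascii("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (dig_max - dig_min) / (2 * phys_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(pmin(dig_max, pmax(dig_min,
        round((rec$signal[ch, idx] + phys_max[ch]) * scale[ch]) + dig_min)))
    }, integer(fs))
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < n)
      stop("format error: truncated EDF header in ", path)
    trimws(out)
  }
  rd(8)                                   # version
  subject <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (any(is.na(c(hdr_bytes, n_rec, rec_dur, ns))) || ns < 1)
    stop("format error: unparseable EDF header in ", path,
         " (byte offset <= 256)")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1 || length(unique(rec_dur)) != 1)
    stop("format error: EDF channels have different sampling rates; ",
         "multi-rate files are not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   signed = TRUE, endian = "little")
    if (length(raw) < ns * spr[1])
      stop("format error: truncated EDF data record ", r, " in ", path)
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns))
      sig[ch, idx] <- (block[, ch] - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch]) +
        phys_min[ch]
  }
  recording(sig, fs, make.unique(labels), subject)
}

# --- annotations -----------------------------------------------------------

#' Write event annotations to CSV
#'
#' Delimited text with header `channel,start_s,end_s,label`, times in
#' seconds.
#'
#' @param ann an `hfo_annotations` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(channel = ann$channel_id, start_s = ann$start,
                    end_s = ann$end, label = ann$label)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read event annotations from CSV
#'
#' Expects the header `channel,start_s,end_s,label`; labels must belong to
#' the three-class vocabulary (R, FR, FRonR) and `end_s > start_s`.
#' Malformed rows are reported with their line number.
#'
#' @param path CSV path
#' @return an `hfo_annotations` data.frame (possibly empty)
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = "channel", numeric = c("start_s", "end_s"),
    character = "label"))
  required <- c("channel", "start_s", "end_s", "label")
  if (!all(required %in% names(dt)))
    stop("format error: annotation file must have header ",
         paste(required, collapse = ","))
  if (nrow(dt) == 0) return(annotations())
  line <- seq_len(nrow(dt)) + 1L           # +1 for the header line
  bad <- which(!dt$label %in% HFO_LABELS)
  if (length(bad))
    stop("unknown label '", dt$label[bad[1]], "' at line ", line[bad[1]])
  bad <- which(!is.finite(dt$start_s) | !is.finite(dt$end_s))
  if (length(bad))
    stop("malformed times at line ", line[bad[1]])
  bad <- which(dt$end_s <= dt$start_s)
  if (length(bad))
    stop("end <= start at line ", line[bad[1]])
  annotations(dt$channel, dt$start_s, dt$end_s, dt$label)
}

# --- feature tables --------------------------------------------------------

#' Write a segment feature table to CSV
#'
#' Stable column order: 5 provenance columns (subject_id, channel_id,
#' segment_start, window_ms, synthetic), the 12 feature columns
#' (band-major), then `label`. Values are written with 15 significant
#' digits so a round trip preserves them beyond 12 digits.
#'
#' @param table a `segment_feature_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0) stop("refusing to write an empty feature table")
  cols <- c(PROVENANCE_COLUMNS, feature_columns(), "label")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("feature table missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"synthetic" %in% names(table)) table$synthetic <- FALSE
  dt <- data.table::as.data.table(table)[, cols, with = FALSE]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a segment feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()]
#' @return a `segment_feature_table`
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  dt <- data.table::fread(path)
  cols <- c(PROVENANCE_COLUMNS, feature_columns(), "label")
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop("format error: feature table missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(dt$label), SEGMENT_LABELS)
  if (length(bad))
    stop("format error: unknown segment label(s): ",
         paste(bad, collapse = ", "))
  tbl <- as.data.frame(dt)
  tbl$subject_id <- as.character(tbl$subject_id)
  tbl$channel_id <- as.character(tbl$channel_id)
  tbl$synthetic <- as.logical(tbl$synthetic)
  class(tbl) <- c("segment_feature_table", "data.frame")
  tbl
}
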