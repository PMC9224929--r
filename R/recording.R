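#' Construct an LFP recording
#'
#' A recording is a uniformly sampled single-channel voltage trace with
#' subject and group metadata. All analysis functions in the package take
#' this container as input. Times are in seconds, anchored at the first
#' sample (t = 0); sample units are arbitrary (thresholds downstream are
#' data-driven, so absolute amplifier calibration is not required).
#'
#' @param samples Numeric vector of voltage samples; all values must be
#'   finite and at least one sample must be present.
#' @param sampling_rate Sampling rate in Hz (> 0). Recordings in this field
#'   are typically digitized at 5 kHz.
#' @param subject_id Subject identifier string.
#' @param group Group label string (e.g. `"wt"`, `"mutant"`).
#' @param acquisition_band Length-2 numeric, the hardware acquisition
#'   band-pass in Hz (low < high). Default `c(0.3, 1300)`, the usual
#'   amplifier setting for larval zebrafish forebrain LFP.
#' @return An object of class `lfp_recording` with fields `samples`,
#'   `sampling_rate`, `subject_id`, `group`, `acquisition_band` and derived
#'   `duration_s = length(samples) / sampling_rate`.
#' @examples
#' rec <- lfp_recording(rnorm(5000), 5000)
#' rec$duration_s  # 1 second
#' @export
lfp_recording <- function(samples, sampling_rate, subject_id = "s1",
                          group = "unknown",
                          acquisition_band = c(0.3, 1300)) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("empty-input error: a recording must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("recording samples must all be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)")
  if (length(acquisition_band) != 2L || acquisition_band[1] >= acquisition_band[2])
    stop("acquisition_band must be (low, high) with low < high")
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         group = as.character(group),
         acquisition_band = as.numeric(acquisition_band),
         duration_s = length(samples) / sampling_rate),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> subject=%s group=%s\n", x$subject_id, x$group))
  cat(sprintf("  %d samples @ %g Hz (%.3f s), acquisition band %g-%g Hz\n",
              length(x$samples), x$sampling_rate, x$duration_s,
              x$acquisition_band[1], x$acquisition_band[2]))
  invisible(x)
}

# binary-f32 container: 64-byte header then little-endian float32 payload.
# Header: magic "LFP1" (4 bytes), rate as float64, n_samples as uint64
# (written as two little-endian uint32 words), 44 reserved zero bytes.
.lfp1_header_size <- 64L

#' Read a recording from disk
#'
#' Supported formats: `csv` (columns `time_s,value`, or a single `value`
#' column plus a declared `sampling_rate`), `binary-f32` (the package's
#' compact little-endian float32 container, bit-stable round trip), and
#' `edf` (European Data Format, read-only, one channel selected by name or
#' index). The reader never resamples: the returned `sampling_rate` is the
#' declared/stored rate. A csv time column must be uniform to within 1 ppm
#' of its median step.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"binary-f32"`, `"edf"`.
#' @param sampling_rate Required for single-column csv; ignored when the
#'   file itself carries the rate.
#' @param subject_id,group Metadata attached to the returned recording
#'   (binary-f32 does not store them; csv/edf do not either).
#' @param channel For edf: channel label (string) or 1-based index.
#' @return An [lfp_recording].
#' @export
read_recording <- function(path, format = c("csv", "binary-f32", "edf"),
                           sampling_rate = NULL, subject_id = "s1",
                           group = "unknown", channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
         "csv" = .read_recording_csv(path, sampling_rate, subject_id, group),
         "binary-f32" = .read_recording_lfp1(path, subject_id, group),
         "edf" = read_edf_channel(path, channel = channel,
                                  subject_id = subject_id, group = group))
}

.read_recording_csv <- function(path, sampling_rate, subject_id, group) {
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric"),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("parse error: non-numeric or missing value at data line ", bad[1],
         " of ", path)
  if (ncol(df) == 1L) {
    if (is.null(sampling_rate))
      stop("single-column csv requires a declared sampling_rate")
    return(lfp_recording(df[[1]], sampling_rate, subject_id, group))
  }
  if (!all(c("time_s", "value") %in% names(df)))
    stop("parse error: csv header must be 'time_s,value' or 'value'")
  tt <- df$time_s
  dt <- diff(tt)
  if (length(dt) < 1L) stop("csv must contain at least two rows of samples")
  med <- stats::median(dt)
  if (med <= 0 || any(abs(dt - med) > 1e-6 * med))
    stop("sampling error: time base non-uniform beyond 1 ppm in ", path)
  lfp_recording(df$value, 1 / med, subject_id, group)
}

.read_recording_lfp1 <- function(path, subject_id, group) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(rawToChar(magic), "LFP1"))
    stop("parse error: bad magic bytes in ", path, " (expected 'LFP1')")
  rate <- readBin(con, "double", n = 1L, size = 8L, endian = "little")
  lo <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hi <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  n <- (if (lo < 0) lo + 2^32 else lo) + (if (hi < 0) hi + 2^32 else hi) * 2^32
  readBin(con, "raw", n = .lfp1_header_size - 24L)  # reserved
  x <- readBin(con, "double", n = n, size = 4L, endian = "little")
  if (length(x) != n)
    stop("parse error: truncated payload in ", path, " (expected ", n,
         " samples, got ", length(x), ")")
  lfp_recording(x, rate, subject_id, group)
}

#' Write a recording to disk
#'
#' `binary-f32` round-trips bit-exactly at float32 precision (the samples
#' are stored as little-endian float32, so write followed by read returns
#' exactly the float32-quantized values). `csv` writes with a `'.'` decimal
#' separator regardless of locale. Recordings with zero samples cannot be
#' constructed, and an attempt to write an empty sample vector is refused.
#'
#' @param rec An [lfp_recording].
#' @param path Output path.
#' @param format `"csv"` (columns `time_s,value`) or `"binary-f32"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "binary-f32")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "lfp_recording"))
  if (length(rec$samples) == 0L)
    stop("empty-input error: refusing to write a recording with 0 samples")
  if (format == "csv") {
    tt <- (seq_along(rec$samples) - 1) / rec$sampling_rate
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time_s,value", con)
    # format() with the C locale semantics of sprintf: '.' decimal point
    writeLines(sprintf("%.10g,%.10g", tt, rec$samples), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("LFP1"), con)
    writeBin(as.double(rec$sampling_rate), con, size = 8L, endian = "little")
    n <- length(rec$samples)
    lo <- n %% 2^32; hi <- n %/% 2^32
    as_u32 <- function(v) as.integer(if (v >= 2^31) v - 2^32 else v)
    writeBin(as_u32(lo), con, size = 4L, endian = "little")
    writeBin(as_u32(hi), con, size = 4L, endian = "little")
    writeBin(raw(.lfp1_header_size - 24L), con)
    writeBin(rec$samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read one channel of an EDF file
#'
#' Minimal reader for uncompressed European Data Format (EDF) files: parses
#' the 256-byte fixed header and per-signal headers, then decodes the
#' selected channel's 16-bit samples, applying the physical/digital
#' calibration stored in the header. Multi-rate files are supported (each
#' channel carries its own samples-per-record count); only the selected
#' channel is decoded.
#'
#' @param path EDF file path.
#' @param channel Channel label (exact match against the stored labels,
#'   trailing blanks stripped) or 1-based index.
#' @param subject_id,group Metadata for the returned recording.
#' @return An [lfp_recording].
#' @export
read_edf_channel <- function(path, channel = 1L, subject_id = "s1",
                             group = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) rawToChar(readBin(con, "raw", n = nchars))
  num <- function(nchars) as.numeric(trimws(rd(nchars)))
  rd(8); rd(80); rd(80); rd(8); rd(8)          # version, patient, rec, date, time
  header_bytes <- num(8)
  rd(44)
  n_records <- num(8)
  record_dur <- num(8)
  ns <- as.integer(num(4))
  if (!is.finite(ns) || ns < 1L) stop("parse error: bad EDF signal count")
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(field(16))
  field(80); field(8)                          # transducer, physical dim
  phys_min <- as.numeric(trimws(field(8)))
  phys_max <- as.numeric(trimws(field(8)))
  dig_min <- as.numeric(trimws(field(8)))
  dig_max <- as.numeric(trimws(field(8)))
  field(80)                                    # prefiltering
  spr <- as.integer(trimws(field(8)))          # samples per record
  field(32)                                    # reserved
  if (is.character(channel)) {
    ci <- match(channel, labels)
    if (is.na(ci)) stop("EDF channel not found: ", channel,
                        " (available: ", paste(labels, collapse = ", "), ")")
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > ns) stop("EDF channel index out of range: ", ci)
  }
  seek(con, header_bytes)
  gain <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
  offset <- phys_min[ci] - gain * dig_min[ci]
  before <- if (ci > 1L) sum(spr[seq_len(ci - 1L)]) else 0L
  after <- sum(spr) - before - spr[ci]
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    if (before) readBin(con, "raw", n = 2L * before)
    d <- readBin(con, "integer", n = spr[ci], size = 2L,
                 signed = TRUE, endian = "little")
    if (after) readBin(con, "raw", n = 2L * after)
    out[[r]] <- d
  }
  x <- gain * unlist(out) + offset
  lfp_recording(x, spr[ci] / record_dur, subject_id, group)
}
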