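#' Zero-phase band-pass filter
#'
#' Filters the trace with a 4th-order Butterworth band-pass applied
#' forward-backward (zero-phase), the common practice in electrophysiology:
#' the two-pass application preserves event timing, which matters because
#' event start/end times are read off the filtered power series. Output has
#' identical length and sampling rate. Passband gain is within 5% of unity
#' and stopband gain is below 0.1 at `band_low / 3` and at `2 * band_high`.
#'
#' @param rec An [lfp_recording].
#' @param band_low,band_high Band edges in Hz; `band_high` must be below
#'   the Nyquist frequency.
#' @return A filtered [lfp_recording] (same metadata).
#' @examples
#' fs <- 5000; t <- seq(0, 2, by = 1 / fs)
#' rec <- lfp_recording(sin(2 * pi * 60 * t), fs)
#' filt <- bandpass(rec, 30, 95)  # 60 Hz passes essentially unchanged
#' @export
bandpass <- function(rec, band_low = 30, band_high = 95) {
  stopifnot(inherits(rec, "lfp_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(band_low > 0 && band_high > band_low))
    stop("configuration error: need 0 < band_low < band_high")
  if (band_high >= nyq)
    stop("configuration error: band_high (", band_high,
         " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(4, c(band_low, band_high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, rec$samples)
  out <- rec
  out$samples <- as.numeric(y)
  out
}

#' Rolling RMS band power
#'
#' Computes the root-mean-square of the (already band-filtered) trace over
#' left-aligned, half-open windows `[t, t + window_s)` advanced by
#' `step_s`; this is the per-window activity statistic the whole detection
#' chain operates on. An incomplete trailing window is discarded, so the
#' number of windows is `floor((duration_s - window_s) / step_s) + 1` (for
#' a 15-min recording at 250 ms / 50 ms this is 17,996 windows).
#'
#' @param rec A (band-filtered) [lfp_recording].
#' @param window_s Window length in seconds (<= recording duration).
#' @param step_s Step between window starts in seconds.
#' @return An object of class `power_series`: a list with
#'   `window_start_s`, `rms`, `window_s`, `step_s`, `subject_id`, `group`.
#' @export
rolling_rms <- function(rec, window_s = 0.250, step_s = 0.050) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate
  w <- round(window_s * fs)
  st <- round(step_s * fs)
  if (w < 1L || st < 1L)
    stop("window_s and step_s must each span at least one sample")
  n <- length(rec$samples)
  if (w > n)
    stop("input error: window (", window_s, " s) longer than recording (",
         rec$duration_s, " s)")
  starts <- seq.int(1L, n - w + 1L, by = st)
  cs <- c(0, cumsum(rec$samples^2))
  rms <- sqrt((cs[starts + w] - cs[starts]) / w)
  # guard against tiny negative round-off from the cumsum difference
  rms[rms < 0 | !is.finite(rms)] <- 0
  structure(
    list(window_start_s = (starts - 1L) / fs,
         rms = rms,
         window_s = w / fs, step_s = st / fs,
         subject_id = rec$subject_id, group = rec$group),
    class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf(
    "<power_series> subject=%s group=%s: %d windows (%g s / %g s step)\n",
    x$subject_id, x$group, length(x$rms), x$window_s, x$step_s))
  invisible(x)
}

#' Log10 of the rolling RMS power
#'
#' Returns the log10-transformed window powers, the quantity whose
#' distribution is modeled by the Gaussian machinery. Windows with exactly
#' zero RMS (possible only for an identically-zero stretch of signal) are
#' dropped and counted.
#'
#' @param ps A `power_series`.
#' @return Numeric vector of log10 RMS values with attributes
#'   `n_dropped` (count of zero-power windows removed) and
#'   `zero_variance` (`TRUE` when all retained values are identical, a
#'   guard consumed by the distribution fitters).
#' @export
log_power <- function(ps) {
  stopifnot(inherits(ps, "power_series"))
  pos <- ps$rms > 0
  if (!any(pos))
    stop("degenerate-input error: all windows have zero power")
  lp <- log10(ps$rms[pos])
  attr(lp, "n_dropped") <- sum(!pos)
  attr(lp, "zero_variance") <- isTRUE(max(lp) == min(lp))
  lp
}

#' Export a power series as TSV
#'
#' Columns `window_start_s`, `rms`, `log10_rms` (empty where rms is 0).
#'
#' @param ps A `power_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_series <- function(ps, path) {
  l10 <- ifelse(ps$rms > 0, log10(ps$rms), NA_real_)
  utils::write.table(
    data.frame(window_start_s = ps$window_start_s, rms = ps$rms,
               log10_rms = l10),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
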