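# Independent brute-force oracles and fixture builders used across tests.
# These deliberately use different algorithms from the package code paths.

# Build a power_series object directly from an rms vector.
make_power_series <- function(rms, step_s = 0.05, window_s = 0.25,
                              subject_id = "toy", group = "toy") {
  structure(
    list(window_start_s = (seq_along(rms) - 1) * step_s,
         rms = as.numeric(rms), window_s = window_s, step_s = step_s,
         subject_id = subject_id, group = group),
    class = "power_series")
}

# Per-window RMS by an explicit loop (oracle for rolling_rms).
oracle_rolling_rms <- function(x, fs, window_s, step_s) {
  w <- round(window_s * fs); st <- round(step_s * fs)
  starts <- seq(1, length(x) - w + 1, by = st)
  vapply(starts, function(i) sqrt(mean(x[i:(i + w - 1)]^2)), numeric(1))
}

# Event spans from a logical supra-threshold vector by explicit scanning,
# merging runs separated by <= gap FALSE windows (oracle for extract_events).
oracle_runs <- function(above, gap) {
  out <- list()
  i <- 1L; n <- length(above)
  while (i <= n) {
    if (above[i]) {
      first <- i; last <- i
      j <- i + 1L
      while (j <= n) {
        if (above[j]) { last <- j; j <- j + 1L }
        else {
          # look ahead: bridge if a TRUE occurs within `gap` windows
          k <- j
          while (k <= min(n, j + gap - 1L) && !above[k]) k <- k + 1L
          if (k <= n && above[k] && (k - j) <= gap) { j <- k } else break
        }
      }
      out[[length(out) + 1L]] <- c(first, last)
      i <- j
    } else i <- i + 1L
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_mw_exact <- function(a, b) {
  x <- c(a, b); na <- length(a); n <- length(x)
  u_stat <- function(idx) {
    aa <- x[idx]; bb <- x[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_stat(seq_len(na))
  us <- combn(n, na, u_stat)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Trapezoid AUC between two normal densities by numeric integration of
# P(X_high > X_low) (oracle for the closed form).
oracle_pair_auc <- function(mu1, s1, mu2, s2) {
  # orient so component 2 is the higher mean
  if (mu1 > mu2) { tmp <- mu1; mu1 <- mu2; mu2 <- tmp
                   tmp <- s1; s1 <- s2; s2 <- tmp }
  f <- function(x) dnorm(x, mu2, s2) * pnorm(x, mu1, s1)
  stats::integrate(f, mu2 - 10 * s2, mu2 + 10 * s2, rel.tol = 1e-10)$value
}

# Interval IoU (oracle for score_detection matching decisions).
oracle_iou <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / ((e1 - s1) + (e2 - s2) - inter)
}

# Minimal EDF writer: fixed-width ASCII header + int16 LE records.
# Supports multiple channels with per-channel rates and calibration.
write_edf_fixture <- function(path, channels, record_dur = 1,
                              n_records = 2) {
  pad <- function(s, w) {
    s <- as.character(s)
    if (nchar(s) > w) s <- substr(s, 1, w)
    formatC(s, width = -w)
  }
  ns <- length(channels)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  put("0", 8); put("synthetic test subject", 80)
  put("synthetic edf fixture", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(256 * (1 + ns), 8); put("", 44)
  put(n_records, 8); put(record_dur, 8); put(ns, 4)
  fld <- function(get, w) for (ch in channels) put(get(ch), w)
  fld(function(ch) ch$label, 16)
  fld(function(ch) "", 80)
  fld(function(ch) "uV", 8)
  fld(function(ch) ch$phys_min, 8)
  fld(function(ch) ch$phys_max, 8)
  fld(function(ch) ch$dig_min, 8)
  fld(function(ch) ch$dig_max, 8)
  fld(function(ch) "", 80)
  fld(function(ch) length(ch$digital) / n_records, 8)
  fld(function(ch) "", 32)
  for (r in seq_len(n_records)) {
    for (ch in channels) {
      spr <- length(ch$digital) / n_records
      seg <- ch$digital[((r - 1) * spr + 1):(r * spr)]
      writeBin(as.integer(seg), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
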