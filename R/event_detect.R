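#' Extract supra-threshold events from a power series
#'
#' An event is a maximal run of windows whose log10 RMS power strictly
#' exceeds the detection threshold; runs separated by at most
#' `merge_gap_windows` sub-threshold windows are merged into one event
#' (the default of 1 bridges a single 50 ms power dip inside a polyspike
#' discharge). Time convention, fixed for reproducibility: an event starts
#' at the first supra-threshold window's start time and ends at the last
#' supra-threshold window's start time plus the window length; power
#' metrics are computed over the supra-threshold windows of the run only.
#'
#' @param ps A `power_series` (from [rolling_rms()]).
#' @param threshold_log10 Detection threshold on log10 RMS (typically
#'   `separation_result$threshold_log10`). Must lie within the observed
#'   log-power range +/- 10 SD.
#' @param merge_gap_windows Sub-threshold windows bridged within an event.
#' @param seizure_min_duration_s Passed to [classify_events()].
#' @return An `event_table`: data frame with columns `subject_id`, `group`,
#'   `start_s`, `end_s`, `duration_s`, `mean_rms`, `peak_rms`,
#'   `log10_mean_rms`, `n_windows`, `klass`, plus attributes
#'   `recording_duration_s`, `event_rate_per_min`, `window_s`, `step_s`.
#' @export
extract_events <- function(ps, threshold_log10, merge_gap_windows = 1L,
                           seizure_min_duration_s = 1.0) {
  stopifnot(inherits(ps, "power_series"))
  if (length(ps$rms) == 0L)
    stop("input error: empty power series")
  lp <- ifelse(ps$rms > 0, log10(ps$rms), -Inf)
  fin <- lp[is.finite(lp)]
  if (length(fin) > 1L) {
    s <- stats::sd(fin)
    if (s > 0 &&
        (threshold_log10 > max(fin) + 10 * s ||
         threshold_log10 < min(fin) - 10 * s))
      stop("threshold (", signif(threshold_log10, 4),
           ") lies outside the observed log-power range +/- 10 SD")
  }
  above <- lp > threshold_log10
  runs <- .merge_runs(above, as.integer(merge_gap_windows))
  dur_rec <- utils::tail(ps$window_start_s, 1) + ps$window_s
  ev <- do.call(rbind, lapply(runs, function(r) {
    idx <- r$members                      # supra-threshold windows only
    start_s <- ps$window_start_s[r$first]
    end_s <- ps$window_start_s[r$last] + ps$window_s
    mean_rms <- mean(ps$rms[idx])
    data.frame(
      subject_id = ps$subject_id, group = ps$group,
      start_s = start_s, end_s = end_s, duration_s = end_s - start_s,
      mean_rms = mean_rms, peak_rms = max(ps$rms[idx]),
      log10_mean_rms = log10(mean_rms), n_windows = length(idx),
      klass = NA_character_)
  }))
  if (is.null(ev))
    ev <- data.frame(subject_id = character(), group = character(),
                     start_s = numeric(), end_s = numeric(),
                     duration_s = numeric(), mean_rms = numeric(),
                     peak_rms = numeric(), log10_mean_rms = numeric(),
                     n_windows = integer(), klass = character())
  tbl <- structure(ev, class = c("event_table", "data.frame"),
                   recording_duration_s = dur_rec,
                   event_rate_per_min = 60 * nrow(ev) / dur_rec,
                   window_s = ps$window_s, step_s = ps$step_s,
                   threshold_log10 = threshold_log10,
                   merge_gap_windows = as.integer(merge_gap_windows))
  classify_events(tbl, seizure_min_duration_s)
}

# Runs of TRUE in `above`, merging runs separated by <= gap FALSE windows.
# Each run: first/last window index of the merged span and the indices of
# its supra-threshold members.
.merge_runs <- function(above, gap) {
  idx <- which(above)
  if (!length(idx)) return(list())
  brk <- which(diff(idx) > gap + 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(idx))
  lapply(seq_along(starts), function(k) {
    members <- idx[starts[k]:ends[k]]
    members <- members[above[members]]   # by construction all TRUE
    list(first = members[1], last = members[length(members)],
         members = members)
  })
}

#' Classify events as interictal-like or seizure-like
#'
#' The operational class rule: events strictly longer than
#' `seizure_min_duration_s` (default 1 s) are seizure-like; shorter events
#' (including exactly 1 s) are interictal-like. The boundary is strict
#' because the clinical description is of "long-duration (> 1 s)"
#' discharges.
#'
#' @param tbl An `event_table`.
#' @param seizure_min_duration_s Duration bound in seconds.
#' @return The table with `klass` filled in.
#' @export
classify_events <- function(tbl, seizure_min_duration_s = 1.0) {
  stopifnot(inherits(tbl, "event_table"))
  if (nrow(tbl))
    tbl$klass <- ifelse(tbl$duration_s > seizure_min_duration_s,
                        "seizure_like", "interictal_like")
  attr(tbl, "seizure_min_duration_s") <- seizure_min_duration_s
  tbl
}

#' Per-recording event summary
#'
#' Event count, rate per minute, median and mean of duration and of
#' log10 mean RMS, and counts by class — the per-recording numbers behind
#' the cohort violin plots. Medians/means are `NA` for empty tables.
#'
#' @param tbl An `event_table`.
#' @return One-row `data.frame`.
#' @export
summarize_events <- function(tbl) {
  stopifnot(inherits(tbl, "event_table"))
  n <- nrow(tbl)
  data.frame(
    subject_id = if (n) tbl$subject_id[1] else NA_character_,
    group = if (n) tbl$group[1] else NA_character_,
    n_events = n,
    event_rate_per_min = attr(tbl, "event_rate_per_min"),
    median_duration_s = if (n) stats::median(tbl$duration_s) else NA_real_,
    mean_duration_s = if (n) mean(tbl$duration_s) else NA_real_,
    median_log10_mean_rms = if (n) stats::median(tbl$log10_mean_rms) else NA_real_,
    mean_log10_mean_rms = if (n) mean(tbl$log10_mean_rms) else NA_real_,
    n_interictal_like = sum(tbl$klass == "interictal_like"),
    n_seizure_like = sum(tbl$klass == "seizure_like"))
}

#' Write an event table as TSV
#'
#' Columns `subject_id group start_s end_s duration_s mean_rms peak_rms
#' log10_mean_rms klass`. The detection threshold, gap-merge setting and
#' time convention are recorded as `# key: value` comment lines so the
#' file is self-describing.
#'
#' @param tbl An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# recording_duration_s: %.6g", attr(tbl, "recording_duration_s")),
    sprintf("# threshold_log10: %.10g", attr(tbl, "threshold_log10")),
    sprintf("# merge_gap_windows: %d", attr(tbl, "merge_gap_windows")),
    "# time_convention: start of first window to end of last window; strict > at threshold and class boundary"),
    con)
  cols <- c("subject_id", "group", "start_s", "end_s", "duration_s",
            "mean_rms", "peak_rms", "log10_mean_rms", "klass")
  utils::write.table(as.data.frame(tbl)[cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path TSV path.
#' @return An `event_table` (attributes restored from the comment header).
#' @export
read_event_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln[1]))
  }
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  dur <- getval("recording_duration_s")
  structure(df, class = c("event_table", "data.frame"),
            recording_duration_s = dur,
            event_rate_per_min = 60 * nrow(df) / dur,
            threshold_log10 = getval("threshold_log10"),
            merge_gap_windows = as.integer(getval("merge_gap_windows")))
}
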