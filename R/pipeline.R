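#' Run the full detection chain on one recording
#'
#' Convenience wrapper: band-pass filter, rolling RMS, log-power model
#' selection and thresholding, event extraction and classification.
#'
#' @param rec An [lfp_recording].
#' @param cfg An [analysis_config()].
#' @return List with `power` (the `power_series`), `separation` (the
#'   `separation_result`) and `events` (the classified `event_table`).
#' @examples
#' sim <- simulate_recording(sim_config("mutant", duration_s = 120,
#'                                      sampling_rate = 1000, seed = 7))
#' res <- detect_events(sim$recording)
#' res$separation$mode
#' @export
detect_events <- function(rec, cfg = analysis_config()) {
  filt <- bandpass(rec, cfg$band_low, cfg$band_high)
  ps <- rolling_rms(filt, cfg$window_s, cfg$step_s)
  lp <- log_power(ps)
  sep <- select_model_and_threshold(lp, cfg)
  ev <- extract_events(ps, sep$threshold_log10, cfg$merge_gap_windows,
                       cfg$seizure_min_duration_s)
  list(power = ps, separation = sep, events = ev)
}

#' Batch detection over recording files
#'
#' Processes each input recording through [detect_events()] and writes,
#' per recording, an event table (`<stem>_events.tsv`) and a separation
#' result (`<stem>_separation.json`), plus a run manifest
#' (`manifest.json`) capturing the configuration snapshot, input digests,
#' package version, seed, per-stage timing and output paths — enough to
#' re-run bit-identically. Unreadable recordings are reported and skipped;
#' the manifest then lists them under `errors` and the function signals a
#' warning (a CLI caller maps this to a nonzero exit).
#'
#' @param paths Character vector of recording file paths.
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param format,sampling_rate,channel Passed to [read_recording()].
#' @param groups Optional character vector, one group label per path.
#' @param seed Recorded in the manifest (detection itself is
#'   deterministic).
#' @return Invisibly, the manifest list (with per-recording `mode`, `auc`,
#'   `threshold_log10` in `results`).
#' @export
run_detect <- function(paths, cfg = analysis_config(), out_dir,
                       format = "csv", sampling_rate = NULL, channel = 1L,
                       groups = NULL, seed = NULL) {
  if (!length(paths)) stop("usage error: no input recordings given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); errors <- list(); outputs <- character()
  for (k in seq_along(paths)) {
    p <- paths[k]
    stem <- tools::file_path_sans_ext(basename(p))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      rec <- read_recording(p, format = format,
                            sampling_rate = sampling_rate, channel = channel,
                            subject_id = stem)
      if (!is.null(groups)) rec$group <- groups[k]
      out <- detect_events(rec, cfg)
      ev_path <- file.path(out_dir, paste0(stem, "_events.tsv"))
      sep_path <- file.path(out_dir, paste0(stem, "_separation.json"))
      write_event_table(out$events, ev_path)
      write_separation_result(out$separation, sep_path)
      outputs <- c(outputs, ev_path, sep_path)
      list(input = p, subject_id = stem,
           mode = out$separation$mode, auc = out$separation$auc,
           threshold_log10 = out$separation$threshold_log10,
           n_events = nrow(out$events),
           elapsed_s = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- list(input = p,
                                             message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  manifest <- list(
    tool = "lfpburst::run_detect",
    version = as.character(utils::packageVersion("lfpburst")),
    config = unclass(cfg), seed = seed,
    inputs = lapply(paths, function(p)
      list(path = p, md5 = if (file.exists(p)) unname(tools::md5sum(p))
                           else NA_character_)),
    results = results, errors = errors, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (length(errors))
    warning(length(errors), " recording(s) failed: ",
            paste(vapply(errors, `[[`, "", "input"), collapse = ", "))
  invisible(manifest)
}

#' Compare groups from event tables or an endpoint table
#'
#' Dispatches the group design: Mann-Whitney for two groups,
#' Kruskal-Wallis with Dunn post-hoc for three or more. For event tables
#' the comparison unit is either the pooled event (`unit = "events"`, the
#' default — every detected event is one observation) or the per-subject
#' median (`unit = "subjects"`, statistically more conservative since
#' animals, not events, are the independent replicates).
#'
#' @param x A list of `event_table`s, or an `endpoint_table`.
#' @param metric For event tables: `"log10_mean_rms"` (event power),
#'   `"duration_s"`, or any numeric event column. Ignored for endpoint
#'   tables (the `value` column is compared).
#' @param unit `"events"` or `"subjects"` (event tables only).
#' @param adjust Dunn adjustment for k-group designs.
#' @return A `comparison_result`.
#' @export
run_compare <- function(x, metric = "log10_mean_rms",
                        unit = c("events", "subjects"),
                        adjust = "holm") {
  unit <- match.arg(unit)
  if (inherits(x, "endpoint_table")) {
    df <- data.frame(group = as.character(x$group), value = x$value)
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "event_table")))
    pooled <- do.call(rbind, lapply(x, as.data.frame))
    if (!nrow(pooled)) stop("no events in any table")
    if (!metric %in% names(pooled)) stop("unknown event metric: ", metric)
    if (unit == "events") {
      df <- data.frame(group = pooled$group, value = pooled[[metric]])
    } else {
      ag <- stats::aggregate(pooled[[metric]],
                             by = list(subject_id = pooled$subject_id,
                                       group = pooled$group),
                             FUN = stats::median)
      df <- data.frame(group = ag$group, value = ag$x)
    }
  }
  groups <- split(df$value, df$group)
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L)
    stop("design error: need at least 2 groups with data")
  if (length(groups) == 2L) {
    res <- mann_whitney(groups[[1]], groups[[2]])
    names(res$n_per_group) <- names(res$group_medians) <- names(groups)
    res
  } else {
    kruskal_dunn(groups, adjust = adjust)
  }
}

#' Evaluate detection against ground truth across recordings
#'
#' Pairs each detected event table with its truth table (by list names or
#' position) and reports per-recording and pooled precision/recall/F1.
#' Pooled metrics aggregate matched/detected/truth counts over recordings
#' before forming ratios.
#'
#' @param detected List of `event_table`s.
#' @param truths List of `sim_truth` tables, same length/names.
#' @param min_overlap IoU threshold for a match.
#' @return List with `per_recording` (data frame) and `pooled`
#'   (`detection_score`-like list).
#' @export
run_evaluate <- function(detected, truths, min_overlap = 0.5) {
  if (length(detected) != length(truths))
    stop("pairing error: ", length(detected), " event table(s) vs ",
         length(truths), " truth table(s)")
  if (!is.null(names(detected)) && !is.null(names(truths))) {
    missing <- setdiff(names(detected), names(truths))
    if (length(missing))
      stop("pairing error: no truth for subject ",
           paste(missing, collapse = ", "))
    truths <- truths[names(detected)]
  }
  per <- lapply(seq_along(detected), function(i) {
    s <- score_detection(detected[[i]], truths[[i]], min_overlap)
    data.frame(recording = if (!is.null(names(detected)))
                 names(detected)[i] else as.character(i),
               n_detected = s$n_detected, n_truth = s$n_truth,
               n_matched = s$n_matched, precision = s$precision,
               recall = s$recall, f1 = s$f1)
  })
  per <- do.call(rbind, per)
  nd <- sum(per$n_detected); nt <- sum(per$n_truth); nm <- sum(per$n_matched)
  precision <- if (nd) nm / nd else 1
  recall <- if (nt) nm / nt else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(per_recording = per,
       pooled = list(n_detected = nd, n_truth = nt, n_matched = nm,
                     precision = precision, recall = recall, f1 = f1))
}
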