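#' Analysis configuration
#'
#' Bundles every tunable of the detection chain. The defaults are the
#' standard protocol for larval zebrafish gamma-band burst analysis:
#' 30-95 Hz band, 250 ms rolling windows stepped by 50 ms, a 3-SD burst
#' threshold for unimodal log-power distributions, an AUC > 0.9 gate for
#' accepting a two-component decomposition, and a 1 s duration bound
#' separating seizure-like from interictal-like events.
#'
#' @param band_low,band_high Analysis band edges in Hz.
#' @param window_s Rolling RMS window length in seconds.
#' @param step_s Window step in seconds (0 < step_s <= window_s).
#' @param sd_multiplier Unimodal threshold = mean + `sd_multiplier` * SD of
#'   log10 power.
#' @param auc_min Minimum between-component AUC for accepting the bimodal
#'   model (0.5-1).
#' @param seizure_min_duration_s Events strictly longer than this are
#'   classified seizure-like.
#' @param merge_gap_windows Number of consecutive sub-threshold windows
#'   bridged inside one event (0 = strict runs).
#' @param alpha_levels Descending significance tiers mapped to
#'   `*`, `**`, `***`, `****`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(band_low = 30, band_high = 95,
                            window_s = 0.250, step_s = 0.050,
                            sd_multiplier = 3, auc_min = 0.9,
                            seizure_min_duration_s = 1.0,
                            merge_gap_windows = 1L,
                            alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  stopifnot(band_low > 0, band_high > band_low,
            step_s > 0, step_s <= window_s,
            sd_multiplier > 0,
            auc_min >= 0.5, auc_min <= 1,
            seizure_min_duration_s > 0,
            merge_gap_windows >= 0,
            all(diff(alpha_levels) < 0))
  structure(
    list(band_low = band_low, band_high = band_high,
         window_s = window_s, step_s = step_s,
         sd_multiplier = sd_multiplier, auc_min = auc_min,
         seizure_min_duration_s = seizure_min_duration_s,
         merge_gap_windows = as.integer(merge_gap_windows),
         alpha_levels = alpha_levels),
    class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<analysis_config> band %g-%g Hz, window %g s / step %g s,\n",
    "  %g-SD unimodal rule, AUC gate %g, seizure bound > %g s, gap merge %d\n"),
    x$band_low, x$band_high, x$window_s, x$step_s, x$sd_multiplier,
    x$auc_min, x$seizure_min_duration_s, x$merge_gap_windows))
  invisible(x)
}

#' Read an analysis configuration from a flat key = value file
#'
#' The file format is a flat TOML-compatible subset: one `key = value` pair
#' per line, `#` comments, bare numbers, booleans, quoted strings, and
#' bracketed numeric arrays. Keys mirror the arguments of
#' [analysis_config()]; `overrides` (a named list, e.g. parsed CLI flags)
#' take precedence over file values.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else parse_flat_toml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Parse a flat key = value (TOML subset) file
#'
#' @param path File path.
#' @return Named list of parsed values.
#' @keywords internal
#' @export
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("config parse error in ", path, " at line: ", ln)
    out[[m[2]]] <- .parse_toml_value(trimws(m[3]), path, ln)
  }
  out
}

.parse_toml_value <- function(v, path, ln) {
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  if (grepl("^\\[.*\\]$", v)) {
    parts <- trimws(strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) stop("config parse error: bad array in ", path, ": ", ln)
    return(num)
  }
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) stop("config parse error: bad value in ", path, ": ", ln)
  num
}
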