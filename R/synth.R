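#' Simulation configuration for synthetic LFP recordings
#'
#' Describes a synthetic 15-minute larval-zebrafish-like LFP recording:
#' colored-noise background (power spectral density ~ 1/f^alpha) plus
#' sparse gamma-band (30-95 Hz) discharges of two duration classes —
#' sub-second interictal-like bursts and supra-second seizure-like
#' discharges. The built-in profiles encode the qualitative group contrast
#' the analysis chain is meant to resolve:
#'
#' * `wt`: rare small bursts (0.5/min, amplitude 2 x background SD), no
#'   seizure-like events — yielding a unimodal log-power distribution;
#' * `mutant`: frequent interictal-like bursts (2/min, amplitude 3) plus
#'   seizure-like discharges (0.2/min, amplitude 5, 1.5-5 s) — yielding a
#'   right-skewed, effectively bimodal log-power distribution;
#' * `mutant_treated`: the mutant profile with rates and amplitudes scaled
#'   by 0.4, emulating a treatment that attenuates (without abolishing)
#'   the discharges.
#'
#' Event rates and amplitudes are simulator choices that reproduce the
#' direction and detectability of the group contrast, not measured
#' effect sizes.
#'
#' @param profile `"wt"`, `"mutant"`, `"mutant_treated"` or `"custom"`.
#' @param duration_s Recording length in seconds (default 900 = 15 min).
#' @param sampling_rate Hz (default 5000; 1000 is adequate for the
#'   30-95 Hz analysis band and much faster).
#' @param background List: `alpha` (spectral exponent, default 1),
#'   `sd` (background SD in signal units, default 1).
#' @param interictal List: `rate_per_min`, `amp_mult` (peak amplitude as a
#'   multiple of background SD), `meanlog`/`sdlog` of the lognormal
#'   duration distribution, truncated below 1 s.
#' @param seizure List: `rate_per_min`, `amp_mult`, `dur_min`/`dur_max`
#'   (uniform duration bounds, > 1 s).
#' @param band Carrier band in Hz for the discharge oscillation.
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   recordings.
#' @return A `sim_config` object.
#' @export
sim_config <- function(profile = c("wt", "mutant", "mutant_treated", "custom"),
                       duration_s = 900, sampling_rate = 5000,
                       background = list(alpha = 1, sd = 1),
                       interictal = NULL, seizure = NULL,
                       band = c(30, 95), seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    wt = list(
      interictal = list(rate_per_min = 0.5, amp_mult = 2,
                        meanlog = log(0.3), sdlog = 0.35),
      seizure = list(rate_per_min = 0, amp_mult = 5,
                     dur_min = 1.5, dur_max = 5)),
    mutant = list(
      interictal = list(rate_per_min = 2, amp_mult = 3,
                        meanlog = log(0.3), sdlog = 0.35),
      seizure = list(rate_per_min = 0.2, amp_mult = 5,
                     dur_min = 1.5, dur_max = 5)),
    mutant_treated = list(
      interictal = list(rate_per_min = 2 * 0.4, amp_mult = 3 * 0.4,
                        meanlog = log(0.3), sdlog = 0.35),
      seizure = list(rate_per_min = 0.2 * 0.4, amp_mult = 5 * 0.4,
                     dur_min = 1.5, dur_max = 5)),
    custom = list(
      interictal = list(rate_per_min = 0, amp_mult = 2,
                        meanlog = log(0.3), sdlog = 0.35),
      seizure = list(rate_per_min = 0, amp_mult = 5,
                     dur_min = 1.5, dur_max = 5)))
  interictal <- utils::modifyList(defaults$interictal,
                                  if (is.null(interictal)) list() else interictal)
  seizure <- utils::modifyList(defaults$seizure,
                               if (is.null(seizure)) list() else seizure)
  if (profile == "wt" && seizure$rate_per_min != 0)
    stop("wt profile requires a zero seizure rate")
  stopifnot(duration_s > 0, sampling_rate > 0,
            background$alpha >= 0, background$sd > 0,
            interictal$rate_per_min >= 0, interictal$amp_mult > 0,
            seizure$rate_per_min >= 0, seizure$amp_mult > 0,
            seizure$dur_min > 1, seizure$dur_max >= seizure$dur_min,
            band[1] > 0, band[2] > band[1], band[2] < sampling_rate / 2)
  structure(list(profile = profile, duration_s = duration_s,
                 sampling_rate = sampling_rate, background = background,
                 interictal = interictal, seizure = seizure,
                 band = band, seed = as.integer(seed)),
            class = "sim_config")
}

# 1/f^alpha colored noise via spectral shaping of white Gaussian noise;
# spectrum flattened below 1 Hz to keep the low-frequency variance finite.
.colored_noise <- function(n, fs, alpha, sd_target) {
  x <- stats::rnorm(n)
  if (alpha == 0) return(sd_target * x)
  xf <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)               # two-sided (mirror) frequencies
  shape <- pmax(f, 1)^(-alpha / 2)
  shape[1] <- 0                      # remove DC
  y <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  sd_target * y / stats::sd(y)
}

#' Simulate one LFP recording with ground truth
#'
#' Background: colored noise with the configured spectral slope. Events:
#' Hann-enveloped sinusoidal bursts with carrier frequency drawn uniformly
#' inside the configured band, placed at Poisson-process times, with
#' candidate placements rejected until no two events overlap (0.5 s guard
#' gap). Identical seeds give bit-identical output. A configuration whose
#' expected event load exceeds half the recording is rejected as
#' infeasible.
#'
#' @param cfg A [sim_config()].
#' @return List with `recording` (an [lfp_recording], group = profile) and
#'   `truth` (a `sim_truth` data frame: `start_s`, `end_s`, `klass`,
#'   `amplitude_multiplier`, `carrier_hz`).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  n <- round(cfg$duration_s * fs)
  exp_load <- cfg$duration_s / 60 *
    (cfg$interictal$rate_per_min * exp(cfg$interictal$meanlog) +
     cfg$seizure$rate_per_min *
       (cfg$seizure$dur_min + cfg$seizure$dur_max) / 2)
  if (exp_load > 0.5 * cfg$duration_s)
    stop("infeasible-config error: expected event load exceeds 50% of the recording")
  x <- .colored_noise(n, fs, cfg$background$alpha, cfg$background$sd)

  n_int <- stats::rpois(1, cfg$interictal$rate_per_min * cfg$duration_s / 60)
  n_sei <- stats::rpois(1, cfg$seizure$rate_per_min * cfg$duration_s / 60)
  dur_int <- if (n_int) .rlnorm_below(n_int, cfg$interictal$meanlog,
                                      cfg$interictal$sdlog, 1) else numeric()
  dur_sei <- if (n_sei) stats::runif(n_sei, cfg$seizure$dur_min,
                                     cfg$seizure$dur_max) else numeric()
  durs <- c(dur_sei, dur_int)             # place long events first
  klass <- rep(c("seizure_like", "interictal_like"), c(n_sei, n_int))
  amps <- rep(c(cfg$seizure$amp_mult, cfg$interictal$amp_mult),
              c(n_sei, n_int))
  placed <- matrix(numeric(), ncol = 2)
  keep <- logical(length(durs))
  starts <- numeric(length(durs))
  guard <- 0.5
  for (i in seq_along(durs)) {
    for (try in seq_len(1000L)) {
      s <- stats::runif(1, 0, cfg$duration_s - durs[i])
      e <- s + durs[i]
      if (!nrow(placed) ||
          all(e + guard <= placed[, 1] | s - guard >= placed[, 2])) {
        placed <- rbind(placed, c(s, e))
        starts[i] <- s; keep[i] <- TRUE
        break
      }
    }
  }
  truth <- data.frame(start_s = starts[keep], end_s = starts[keep] + durs[keep],
                      klass = klass[keep],
                      amplitude_multiplier = amps[keep],
                      carrier_hz = rep(NA_real_, sum(keep)))
  ord <- order(truth$start_s)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  for (i in seq_len(nrow(truth))) {
    fc <- stats::runif(1, cfg$band[1] + 5, cfg$band[2] - 5)
    ph <- stats::runif(1, 0, 2 * pi)
    truth$carrier_hz[i] <- fc
    i0 <- round(truth$start_s[i] * fs) + 1L
    i1 <- min(round(truth$end_s[i] * fs), n)
    idx <- i0:i1
    tt <- (idx - i0) / fs
    env <- 0.5 * (1 - cos(2 * pi * tt / (truth$end_s[i] - truth$start_s[i])))
    x[idx] <- x[idx] + truth$amplitude_multiplier[i] * cfg$background$sd *
      env * sin(2 * pi * fc * tt + ph)
  }
  class(truth) <- c("sim_truth", "data.frame")
  rec <- lfp_recording(x, fs,
                       subject_id = sprintf("%s_seed%d", cfg$profile, cfg$seed),
                       group = cfg$profile)
  list(recording = rec, truth = truth)
}

# lognormal draws truncated to (0, upper) by rejection
.rlnorm_below <- function(n, meanlog, sdlog, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, d[d < upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of recordings
#'
#' Per-subject seeds are derived reproducibly from `base_seed`, and each
#' subject's event rates and amplitudes are jittered by up to +/-10%
#' (uniform) to mimic between-animal variability. The same `base_seed`
#' always reproduces the identical cohort, and the cohort is extensible:
#' subject k's data do not depend on `n_subjects`.
#'
#' @param profile Simulation profile (see [sim_config()]).
#' @param n_subjects Number of animals (>= 1).
#' @param base_seed Integer cohort seed.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `duration_s`, `sampling_rate`).
#' @return List of `n_subjects` elements, each as from
#'   [simulate_recording()]; subject ids are `<profile>_01`, ...
#' @export
simulate_cohort <- function(profile, n_subjects, base_seed = 1L, ...) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    subj_seed <- .derive_seed(base_seed, i)
    set.seed(subj_seed)
    jit <- stats::runif(4, 0.9, 1.1)
    cfg0 <- sim_config(profile = profile, seed = 1L, ...)
    cfg <- sim_config(
      profile = "custom",
      duration_s = cfg0$duration_s, sampling_rate = cfg0$sampling_rate,
      background = cfg0$background,
      interictal = utils::modifyList(cfg0$interictal, list(
        rate_per_min = cfg0$interictal$rate_per_min * jit[1],
        amp_mult = cfg0$interictal$amp_mult * jit[2])),
      seizure = utils::modifyList(cfg0$seizure, list(
        rate_per_min = cfg0$seizure$rate_per_min * jit[3],
        amp_mult = cfg0$seizure$amp_mult * jit[4])),
      band = cfg0$band,
      seed = .derive_seed(subj_seed, 1L))
    out <- simulate_recording(cfg)
    out$recording$subject_id <- sprintf("%s_%02d", profile, i)
    out$recording$group <- profile
    out
  })
}

# deterministic 31-bit seed derivation (splitmix-style integer mix)
.derive_seed <- function(base, k) {
  v <- (as.numeric(base) * 2654435761 + as.numeric(k) * 40503 + 12345) %%
    2147483647
  as.integer(max(v, 1))
}

#' Simulate behavioral endpoint tables
#'
#' Draws per-subject endpoint values (e.g. distance traveled, coil counts)
#' from a truncated-at-zero normal per group — behavioral read-outs are
#' nonnegative by construction.
#'
#' @param profiles Named list mapping group label to
#'   `list(mean =, sd =, n =)`.
#' @param endpoint_name Endpoint label stored in the table.
#' @param seed Integer seed.
#' @return An `endpoint_table`.
#' @export
simulate_endpoints <- function(profiles, endpoint_name = "distance_traveled",
                               seed = 1L) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  set.seed(seed)
  rows <- lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    stopifnot(p$sd >= 0, p$n >= 1)
    vals <- numeric(p$n)
    for (i in seq_len(p$n)) {
      repeat {
        v <- stats::rnorm(1, p$mean, p$sd)
        if (v >= 0) break
      }
      vals[i] <- v
    }
    data.frame(subject_id = sprintf("%s_%03d", g, seq_len(p$n)),
               group = g, endpoint = endpoint_name, value = vals)
  })
  as_endpoint_table(do.call(rbind, rows), groups = names(profiles),
                    origin = "simulate_endpoints")
}

#' Score detected events against simulation ground truth
#'
#' One-to-one greedy matching by decreasing temporal
#' intersection-over-union (IoU); a detected/truth pair matches iff their
#' IoU is at least `min_overlap`. Precision = matched / detected, recall =
#' matched / truth, F1 their harmonic mean. With zero detections precision
#' is undefined and reported as 1 with `zero_detected = TRUE` (and
#' symmetrically for empty truth).
#'
#' @param detected An `event_table` (or data frame with `start_s`,
#'   `end_s`).
#' @param truth A `sim_truth` data frame.
#' @param min_overlap IoU threshold in (0, 1].
#' @return A `detection_score` list: `n_detected`, `n_truth`, `n_matched`,
#'   `precision`, `recall`, `f1`, `zero_detected`, `zero_truth`,
#'   `matches` (data frame of matched index pairs and IoU).
#' @export
score_detection <- function(detected, truth, min_overlap = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  matches <- data.frame(detected = integer(), truth = integer(),
                        iou = numeric())
  if (nd && nt) {
    iou <- outer(seq_len(nd), seq_len(nt), function(i, j) {
      s1 <- detected$start_s[i]; e1 <- detected$end_s[i]
      s2 <- truth$start_s[j]; e2 <- truth$end_s[j]
      inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
      union <- (e1 - s1) + (e2 - s2) - inter
      inter / union
    })
    repeat {
      best <- which.max(iou)
      if (!length(best) || iou[best] < min_overlap || is.na(iou[best])) break
      i <- (best - 1) %% nd + 1
      j <- (best - 1) %/% nd + 1
      matches <- rbind(matches,
                       data.frame(detected = i, truth = j, iou = iou[best]))
      iou[i, ] <- -1; iou[, j] <- -1
    }
  }
  nm <- nrow(matches)
  precision <- if (nd) nm / nd else 1
  recall <- if (nt) nm / nt else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(n_detected = nd, n_truth = nt, n_matched = nm,
                 precision = precision, recall = recall, f1 = f1,
                 zero_detected = nd == 0L, zero_truth = nt == 0L,
                 matches = matches),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf(
    "<detection_score> detected=%d truth=%d matched=%d  P=%.3f R=%.3f F1=%.3f\n",
    x$n_detected, x$n_truth, x$n_matched, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Write / read simulation ground truth as TSV
#'
#' Columns `start_s  end_s  klass  amplitude_multiplier  carrier_hz`.
#'
#' @param truth A `sim_truth` data frame.
#' @param path File path.
#' @return `path` (write) or the `sim_truth` (read).
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulation configuration as a flat TOML file
#'
#' Nested fields are flattened to dotted keys (`background.alpha`,
#' `interictal.rate_per_min`, ...), the subset of TOML that
#' [parse_flat_toml()] reads back.
#'
#' @param cfg A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  fmt <- function(key, v) {
    if (is.character(v)) sprintf('%s = "%s"', key, v)
    else if (length(v) > 1)
      sprintf("%s = [%s]", key, paste(format(v, digits = 15), collapse = ", "))
    else sprintf("%s = %s", key, format(v, digits = 15))
  }
  lines <- character()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v)) {
      for (sub in names(v))
        lines <- c(lines, fmt(paste(nm, sub, sep = "."), v[[sub]]))
    } else {
      lines <- c(lines, fmt(nm, v))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("sim_truth", "data.frame")
  df
}
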