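---
title: "Detecting and quantifying seizure-like events in larval zebrafish LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying seizure-like events in larval zebrafish LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpburst)
```

## The measurement problem

Forebrain LFP recordings from larval zebrafish epilepsy models contain
spontaneous epileptiform discharges: short interictal-like bursts and
longer seizure-like events, both visible as transient high power in the
gamma (30–95 Hz) band riding on a 1/f-like background. The analysis task
is to (i) reduce a 15-minute voltage trace to a per-window activity
statistic, (ii) decide, per recording, whether the distribution of that
statistic carries a distinct high-energy population, (iii) place a
detection threshold accordingly, and (iv) convert threshold crossings into
events whose duration and power can be compared across genotype and
treatment groups. Every stage of `lfpburst` is deterministic given its
inputs, so a configuration snapshot reproduces a run bit-for-bit.

## From trace to log-power distribution

The trace is band-passed with a 4th-order Butterworth filter applied
forward–backward. Zero-phase filtering matters here because event times
are read off the filtered signal; a causal filter would shift every event
by its group delay. The filter realization is a package choice — any
filter with flat passband response and strong stopband rejection gives
equivalent downstream results, since all thresholds are data-driven.
Edge transients are retained: for 15-minute recordings the first and last
window contribute a negligible fraction of windows, and zero-phase
filtering keeps the distortion small.

RMS power is computed on left-aligned, half-open windows $[t, t+W)$ with
$W = 250$ ms advanced in $s = 50$ ms steps; an incomplete trailing window
is dropped, giving $\lfloor (T - W)/s \rfloor + 1$ windows (17,996 for
$T = 900$ s). "RMS power" here is the root-mean-square amplitude itself,
not its square; the two conventions differ by a factor of 2 on the log
scale and are monotone-equivalent, so the choice only rescales thresholds
fitted to the same data. Windows with exactly zero RMS (possible only for
an identically zero signal stretch) are dropped with a count, and a
zero-variance log-power vector is refused by the fitters rather than
producing a degenerate model.

## One Gaussian or two

The per-recording decision mimics, reproducibly, the judgement "is this
log-power distribution normally distributed, or asymmetric with a
high-energy population?". Both models are always fitted to the raw
log-power values by maximum likelihood (bin-free; no histogram
artifacts):

* one Gaussian — closed-form MLE ($\hat\mu$, $\hat\sigma$ with
  denominator $n$);
* two Gaussians — EM with deterministic initialization at the 25th and
  97.5th percentiles, pooled SD for both components, weights
  $(0.95, 0.05)$, a relative log-likelihood tolerance of $10^{-6}$, at
  most 500 iterations, and a floor of $10^{-6}\hat\sigma$ on component
  SDs to prevent collapse onto a single point. The initialization encodes
  the expected structure — a dominant background mode plus a rare
  high-power population — and makes the fit seed-independent.

The two-component read-out is accepted only when all three gates hold:

1. BIC of the mixture (5 parameters) below the BIC of the single Gaussian
   (2 parameters);
2. ideal-observer separation
   $\mathrm{AUC} = \Phi\!\left(\frac{\mu_2-\mu_1}{\sqrt{\sigma_1^2+\sigma_2^2}}\right) > 0.9$,
   i.e. a threshold test discriminating the fitted components would be
   near-perfect;
3. minor-component weight $\geq 0.005$, so that the "high-energy
   population" holds at least half a percent of windows rather than being
   a tail artifact.

The AUC is always computed with the higher-mean component as the positive
class, so it is $\geq 0.5$ by construction. The parametric ROC curve
(512 threshold points spanning $\pm 8$ SD around both means) is reported
alongside; its trapezoidal area agrees with the closed form to well below
$10^{-3}$, which the test suite verifies on a random parameter grid.

**Threshold.** In bimodal mode the threshold is the crossing of the two
*weighted* component densities between the means — the equal-posterior
(Bayes) boundary of the fitted model, found by root-finding on the
log-density difference, which changes sign exactly once in
$(\mu_1, \mu_2)$ when a crossing exists. If no crossing exists there
(possible when one component is broad and heavy), the recording falls
back to the unimodal rule. In unimodal mode the threshold is
$\hat\mu + 3\hat\sigma$; for truly Gaussian log-power this passes a
fraction $1-\Phi(3) \approx 0.00135$ of windows, and the acceptance
battery confirms this calibration on $10^6$ simulated windows.

## Events and classes

Events are maximal runs of windows with log-power strictly above the
threshold; runs separated by at most one sub-threshold window (50 ms) are
merged, because polyspike discharges commonly dip briefly mid-event. The
merge depth is configurable (`merge_gap_windows = 0` gives strict runs).
Conventions fixed for reproducibility, and recorded in every output file:
an event spans from the first supra-threshold window's start to the last
supra-threshold window's start plus the window length; comparisons are
strict (`>`) both at the threshold and at the 1 s class boundary, so an
event of exactly 1.0 s is interictal-like. Power metrics (mean and peak
window RMS) are computed over the supra-threshold windows only, excluding
bridged gap windows. Event "power" is reported primarily as
$\log_{10}(\text{mean window RMS})$ with the peak as a secondary metric.

A subtlety worth documenting: neither event count nor summed event span is
individually monotone in the threshold, because raising the threshold can
split one run into two and each span includes a fixed window-length term.
The monotone quantity — which the property tests assert — is the total
supra-threshold window coverage.

## Group statistics

Two-group comparisons use the Mann–Whitney test: exact (full enumeration)
when the combined sample is at most 20 without ties, the tie-corrected
normal approximation with continuity correction otherwise. Multi-arm
designs use Kruskal–Wallis with tie correction followed by Dunn's pairwise
z tests on mean ranks; the post-hoc p values are Holm-adjusted by default
(family-wise error control, uniformly more powerful than Bonferroni, which
remains selectable). Significance tiers map to the conventional
`*`/`**`/`***`/`****` stars at 0.05, 0.01, 0.001, 0.0001.

For event metrics the default comparison unit is the pooled event — every
detected event across all animals of a group is one observation. This
matches how violin-plot cohorts of events are usually presented, but it
treats events from the same fish as independent; the more conservative
per-animal analysis (median per fish, `unit = "subjects"`) is provided
behind a flag, and neither is claimed to be canonical.

## The synthetic cohort generator

The generator provides what public data cannot (raw recordings for this
kind of study are rarely deposited): recordings with known ground truth.
It emulates exactly the statistical structure the detector relies on —

* background: Gaussian colored noise with power spectral density
  $\propto 1/f^{\alpha}$ ($\alpha = 1$ by default, flattened below 1 Hz to
  keep variance finite), unit SD;
* discharges: Hann-enveloped sinusoids with carrier frequency drawn
  uniformly within 35–90 Hz, placed at Poisson times with a 0.5 s guard
  gap and rejection of overlaps;
* `wt`: interictal-like bursts only, 0.5/min, amplitude 2× background SD,
  lognormal durations (median 0.3 s, log-SD 0.35, truncated below 1 s) —
  few enough supra-threshold windows that the minor-weight gate keeps the
  recording on the unimodal path;
* `mutant`: interictal 2/min at 3×, plus seizure-like discharges 0.2/min
  at 5×, uniform 1.5–5 s durations — a right-skewed, effectively bimodal
  log-power distribution;
* `mutant_treated`: mutant rates and amplitudes scaled by 0.4, emulating
  attenuation without abolition.

Rates and amplitudes are simulator choices that reproduce the direction
and detectability of the group contrast; real effect sizes for such
cohorts are published only graphically, so no magnitude claims attach to
them. Cohort simulation derives per-subject seeds from the base seed with
an integer mix (so cohorts are reproducible and extensible) and jitters
each subject's rates and amplitudes by ±10%.

What the generator does **not** emulate: discharge morphology
(spike-wave shape, chirps), nonstationary background (drift, movement
artifacts), electrode noise, or inter-event dependence. Passing tests
therefore demonstrate that the chain recovers events of the assumed
band-limited kind under stationary colored noise — not robustness to
artifact-laden real recordings.

**Detector scoring.** Detected and true events are matched greedily by
decreasing interval intersection-over-union (IoU), one-to-one, with a
match requiring IoU ≥ 0.5. Fidelity is scored on the seizure class
(detected seizure-like vs injected seizure-like events): for sub-window
interictal bursts (0.15–0.3 s) the detected span is floor-limited by the
250 ms window, which caps their IoU below 0.5 regardless of detector
quality, so an all-event IoU score would measure the window length, not
the detector. With zero detections precision is undefined and reported as
1 with an explicit flag.

## Problem sizes and runtime choices

Validation uses full-length 900 s recordings sampled at 1 kHz — the
30–95 Hz analysis band sits comfortably below the 500 Hz Nyquist, and the
window count (17,996) is identical to 5 kHz acquisition, so all
distributional machinery operates at the true scale. The acceptance
battery runs 100 simulated recordings per profile for detector fidelity,
100 EM replicates at n = 17,996 for mixture recovery, $10^6$ windows for
tail calibration, and 11-animal cohorts for the group contrasts. Unit
tests use shorter (30–600 s) recordings.

## Known limitations

* Single-channel only; no artifact rejection or spike sorting.
* The density-crossing threshold is this package's defined operating
  point for bimodal recordings; other published operating points (e.g.
  fixed specificity on the fitted background component) would shift
  per-event counts without changing the model-selection machinery. An
  empirical (label-based) ROC variant is a possible extension.
* At most two mixture components; recordings with graded multi-state
  activity are forced into background-vs-discharge.
* The EDF reader is minimal (EDF, not EDF+; single channel decoded);
  the native acquisition container of commercial amplifiers is supported
  only via export to csv/binary-f32.
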