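# lfpburst

Quantification of seizure-like brain activity in larval zebrafish from
single-channel local field potential (LFP) recordings.

Larval zebrafish models of genetic epilepsies (e.g. *epm2a* loss-of-function
models of Lafora disease) show spontaneous epileptiform discharges in
forebrain LFP recordings: brief interictal-like bursts and longer
(> 1 s) seizure-like events, both expressed as high power in the 30–95 Hz
band. `lfpburst` implements the complete measurement chain used to turn a
raw 15-minute voltage trace into event counts, event metrics and group
statistics, together with a synthetic LFP cohort generator with ground
truth for validating the detector. It is intended for electrophysiologists
quantifying hyperexcitability phenotypes and for methodologists who need a
reproducible, scriptable reference implementation of this analysis.

## The measurement chain

1. **Band-pass** — zero-phase 4th-order Butterworth filter, 30–95 Hz.
2. **Rolling RMS power** — root-mean-square of the filtered trace on
   250 ms windows stepped by 50 ms; a 15-minute recording yields 17,996
   windows.
3. **Log-power model** — the distribution of `log10(RMS)` is fitted with a
   single Gaussian *and* a two-component Gaussian mixture (EM, deterministic
   initialization). The two-component read-out is accepted only if the BIC
   favors it, the minor component holds at least 0.5% of windows, and the
   ideal-observer ROC area between the components

   AUC = Φ( (μ₂ − μ₁) / √(σ₁² + σ₂²) )

   exceeds 0.9 — otherwise the recording is treated as unimodal.
4. **Threshold** — bimodal mode: the crossing of the two weighted component
   densities between the means (the equal-posterior boundary); unimodal
   mode: μ + 3σ of the single Gaussian.
5. **Events** — maximal supra-threshold window runs (single-window dips
   bridged), with duration, mean/peak RMS, and class: *seizure-like* if
   duration > 1 s, else *interictal-like*.
6. **Statistics** — Mann–Whitney for two groups (exact for small tie-free
   samples), Kruskal–Wallis with Dunn's post-hoc (Holm-adjusted) for
   multi-arm designs, plus violin summary statistics.

## Worked example

```r
library(lfpburst)

# a synthetic mutant-like 15-minute recording at 1 kHz, with ground truth
sim <- simulate_recording(sim_config("mutant", sampling_rate = 1000, seed = 42))
res <- detect_events(sim$recording, analysis_config())

res$separation
#> <separation_result> mode = bimodal_roc, threshold(log10) = -0.2205
#>   between-component AUC = 0.9956 (gate applied per config)
#>   BIC: 1-component -33254.3 vs 2-component -47773.6, n = 17996

summarize_events(res$events)
#>      subject_id  group n_events event_rate_per_min median_duration_s ...
#> 1 mutant_seed42 mutant       36                2.4              0.55 ...

sum(res$events$klass == "seizure_like")
#> [1] 3

score_detection(res$events[res$events$klass == "seizure_like", ],
                sim$truth[sim$truth$klass == "seizure_like", ])
#> <detection_score> detected=3 truth=3 matched=3  P=1.000 R=1.000 F1=1.000
```

The separation result says the log-power distribution of this recording is
bimodal (AUC 0.9956 between components, well above the 0.9 gate), so the
threshold is placed at the density crossing; 36 events are extracted, 3 of
them longer than 1 s and therefore seizure-like — and those 3 match the
injected seizure-like discharges exactly.

Cohort-level comparison works the same way on real or simulated data:

```r
wt  <- lapply(simulate_cohort("wt", 11, 1, sampling_rate = 1000),
              function(s) detect_events(s$recording)$events)
mut <- lapply(simulate_cohort("mutant", 11, 2, sampling_rate = 1000),
              function(s) detect_events(s$recording)$events)
run_compare(c(wt, mut), metric = "duration_s")       # pooled-event Mann–Whitney
run_compare(c(wt, mut), metric = "duration_s", unit = "subjects")  # per-fish medians
```

A thin command-line front end (`inst/cli/lfpburst`) exposes the same chain
as `simulate`, `detect`, `compare` and `evaluate` subcommands.

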