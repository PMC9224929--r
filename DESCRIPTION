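Package: lfpburst
Title: Seizure-Like Event Detection in Larval Zebrafish LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neuronal hyperexcitability in single-channel local
    field potential (LFP) recordings from larval zebrafish. The measurement
    chain band-pass filters the trace in the gamma range (30-95 Hz), computes
    root-mean-square power on rolling windows, models the distribution of
    log10 power with one or two Gaussian components, gates the two-component
    decomposition by the area under the between-component ROC curve, derives
    a detection threshold (density crossing, or mean plus three standard
    deviations for unimodal recordings), extracts supra-threshold events, and
    classifies them as interictal-like or seizure-like by a one-second
    duration rule. Cohort-level contrasts use Mann-Whitney and
    Kruskal-Wallis/Dunn nonparametric tests. A synthetic LFP cohort generator
    with ground-truth event intervals supports detector validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
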