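Package: stmpr
Title: Short-Term Motor Patterns in Rest-Tremor Gyroscope Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and characterization of short-term motor patterns
    (STMPs) in resting hand-tremor angular-velocity recordings. Provides a
    regime-switching synthetic tremor generator (physiological 8-10 Hz and
    parkinsonian 3-6 Hz rest-tremor archetypes with hidden Markov dwell
    dynamics, sensor noise, clipping and ADC quantization), signal
    preprocessing (cubic-spline resampling, Tukey running-median smoothing,
    zero-phase high-pass detrending), windowed feature extraction (mean
    absolute value, coefficient of variation, zero-crossing rate, sample
    entropy, Hjorth activity/mobility/complexity), t-SNE embedding with
    k-means clustering and silhouette/gap-statistic model selection, a
    permutation Fasano-Franceschini two-dimensional two-sample test, Markov
    transition and persistence-time analysis of pattern sequences, and
    group-level statistical characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rtsne,
    cluster,
    nortest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
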