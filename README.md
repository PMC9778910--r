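# stmpr — short-term motor patterns in rest-tremor gyroscope signals

Hand tremor is not a stationary oscillation: within a single 15-second
recording the signal drifts between recurring window-scale states that
differ in amplitude, dominant frequency and predictability. `stmpr`
identifies these **short-term motor patterns (STMPs)** in single-axis
gyroscope angular-velocity recordings (degrees per second) and
characterizes their dynamics, for researchers in movement-disorder signal
analysis comparing physiological tremor (8–10 Hz, low amplitude,
irregular) with parkinsonian rest tremor (3–6 Hz, large, regular).

The pipeline:

1. **Preprocessing** — cubic-spline resampling 50 → 300 Hz, Tukey 3RS3R
   running-median smoothing, linear detrend + zero-phase 4th-order
   Butterworth high-pass (1.5 Hz).
2. **Windowed features** — 1 s windows, 50 % overlap; per window: MAV, CV,
   ZCR, SampEn (m = 2, r = 0.2 sd, Chebyshev), Hjorth activity, mobility,
   complexity.
3. **Unsupervised pattern discovery** — z-score, t-SNE (perplexity 10),
   cluster count by mean silhouette width and the gap statistic, k-means
   (k-means++, 10 restarts), and pairwise cluster separation by a
   permutation **Fasano–Franceschini** two-dimensional two-sample test.
4. **STMP dynamics** — Markov transition matrix
   `p_ij = Pr(X_n = j | X_(n-1) = i)` per group and persistence time
   `D(i) = (n_i / r_i) × 0.06` (member windows over permanence blocks).
5. **Characterization** — per-(feature, STMP) group means ± SD with
   Wilcoxon rank-sum tests between healthy-control (HC) and parkinsonian
   (PD) windows.

Because the clinical recordings this analysis targets are not public, the
package includes a first-class synthetic cohort generator
(`generate_cohort()`): a hidden-Markov regime-switching oscillator model
with per-group dwell dynamics, severity modulation, sensor noise, ±500 dps
clipping and 12-bit quantization. All tests and the acceptance analysis
run against it. See the methods vignette
(`vignettes/stmp-methods.Rmd`) for the model and every numerical decision.

## Worked example

```r
library(stmpr)

res <- run_all(run_config(seed = 1), out_dir = "stmp_run")

res$selection$k
#> [1] 3

res$ff2d
#>   cluster_i cluster_j    d_stat     p_value
#> 1         1         2 0.8608628 0.000999001
#> 2         1         3 0.9283646 0.000999001
#> 3         2         3 0.9130465 0.000999001

subset(res$dynamics$persistence, stmp == 3)
#>   group stmp   n  r      D_ms
#> 3    HC    3 155 49 0.1897959
#> 6    PD    3 636 74 0.5156757
```

Reading: the silhouette/gap selection on the t-SNE map of 2262 windows
recovers the three generated tremor archetypes (`k = 3`); every pair of
STMP clusters is separated at the permutation floor (D close to 1,
p ≈ 0.001 with 1000 permutations); and the PD group dwells in the
highest-amplitude pattern roughly 2.7× longer than controls
(persistence time 0.52 vs 0.19 on the `× 0.06` reporting scale), the
characteristic loss of pattern-switching variability. STMP numbering is
canonical: patterns are sorted by mean member MAV, so STMP 1 is the
low-amplitude physiological pattern and STMP 3 the high-amplitude
parkinsonian one.

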