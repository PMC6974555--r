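# cvhr

Nocturnal heart-rate tachogram analysis for risk stratification after
myocardial infarction.

Sleep-disordered breathing (SDB) leaves a characteristic fingerprint in the
nocturnal heart rate: cyclic variation of heart rate (CVHR), an alternating
bradycardia/tachycardia pattern in which each apnea ends in an arousal with
a transient heart-rate surge.  CVHR can be scored from an ordinary Holter
ECG, which makes it an attractive SDB screen in cardiac patients.  Some
patients, however, show a **flat** nocturnal tachogram — heart-rate
excursions under 5 bpm and no visible respiratory sinus arrhythmia — in
which CVHR scoring is impossible; far from being a nuisance, this flatness
marks severe impairment of cardiac autonomic control and carries a
substantially increased 5-year mortality risk of its own.

`cvhr` implements the full analysis chain for cohorts of post-MI Holter
recordings, for researchers in cardiac electrophysiology and biostatistics:

* **RR-interval handling** — reading beat-annotated RR series
  (`time_s, rr_ms, label` with `N/V/S/X` labels), nocturnal windowing
  (00:00–06:00, half-open, with a coverage check), and normal-to-normal
  (NN) filtering.
* **CVHR scoring** — an automated version of the classical manual rules:
  arousals are HR rises ≥ 6 bpm above the local baseline lasting ≥ 10 s;
  an episode is ≥ 3 successive arousals with ≤ 2 min between them; SDB is
  assumed when CVHR covers ≥ 20 % of the segment (72 min of the 6-h
  night).
* **Flat-tachogram detection** — a deterministic stand-in for visual
  review: robust (0.5th–99.5th percentile) excursion of the smoothed HR
  < 5 bpm and band-limited (0.15–0.40 Hz) RSA amplitude < 1 bpm.
* **Risk-marker panel** — SDNN, SDANN, RMSSD, HRV triangular index,
  spectral band powers (VLF/LF/HF/TP, Welch PSD on a 4-Hz resampled NN
  tachogram), heart-rate turbulence (TO, TS), deceleration capacity
  (phase-rectified signal averaging), and the severe-autonomic-failure
  (SAF) composite: abnormal HRT (TS ≤ 2.5 ms/RR and TO ≥ 0 %) together
  with abnormal DC (≤ 4.5 ms).
* **Survival statistics** — Kaplan–Meier curves with log-log Greenwood
  intervals, log-rank tests, Cox proportional-hazards models (Efron
  ties), a CVHR-threshold mortality scan, and Pearson correlation.
* **A synthetic cohort generator** — nocturnal RR series with planted,
  rule-satisfying apnea–arousal episodes, flat tachograms at realistic
  prevalence, and 5-year proportional-hazards outcomes — so the whole
  pipeline is testable without patient data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for model objects, `autoplot()` for tachograms, survival curves
and the threshold scan.

## Worked example

Score a synthetic night with twelve planted apnea–arousal episodes
(10 cycles each, 45-s period, 8-bpm surges — exactly 84 CVHR minutes by
construction):

```r
library(cvhr)

spec <- tachogram_spec(
  duration_s = 21600,                     # the 6-h nocturnal window
  episodes   = plant_episodes(12, n_cycles = 10, surge_bpm = 8),
  rsa_amplitude_bpm = 2, noise_sd_bpm = 0.5
)
night  <- simulate_tachogram(spec, seed = 42)
tach   <- build_tachogram(nn_filter(night))
result <- score_cvhr(tach)

result$flat
#> # A tibble: 1 × 5
#>   is_flat max_excursion_bpm rsa_amplitude_bpm rsa_present rule_version
#>   <lgl>               <dbl>             <dbl> <lgl>       <chr>
#> 1 FALSE                14.9              1.66 TRUE        robust-percentile-1

nrow(result$episodes); result$cvhr_minutes; result$sdb_status
#> [1] 12
#> [1] 83.9
#> [1] "present"
```

The detector recovers all 12 episodes and 83.9 of the 84 planted CVHR
minutes; since 83.9 ≥ 72, the night is classified as SDB-present.

At cohort level, simulate a statistical twin of a post-MI cohort
(n = 1590, 4.8 % flat prevalence, outcome hazard ratios at the generator
defaults) and fit the multivariable mortality model:

```r
co  <- simulate_cohort(cohort_spec(n = 1590), seed = 1)
fit <- cox_fit(co, time_years, event,
               c("flat", "age", "female", "lvef", "grace", "diabetes"))
tidy(fit)
#> # A tibble: 6 × 7
#>   term     estimate std_error hazard_ratio ci_low ci_high  p_value
#> 1 flat      0.391     0.283          1.48   0.848   2.57  1.68e- 1
#> 2 age       0.0700    0.00858        1.07   1.05    1.09  3.62e-16
#> 3 female   -0.0461    0.189          0.955  0.659   1.38  8.07e- 1
#> 4 lvef     -0.0405    0.00631        0.960  0.949   0.972 1.49e-10
#> 5 grace     0.00434   0.00333        1.00   0.998   1.01  1.93e- 1
#> 6 diabetes  0.570     0.183          1.77   1.23    2.53  1.90e- 3
```

A single cohort is noisy (here the flat hazard ratio is 1.48 with a wide
CI around the generating value 1.73); averaging over replicate cohorts
recovers the generating coefficients — that is what the acceptance script
measures.  Per-patient scoring of whole recordings goes through
`run_patient()`, cohort-level bundles (group sizes, KM curves, log-rank
tests, the threshold scan, the Cox model, the SAF cross-tabulation)
through `run_cohort()`, and a thin command-line front end is available at
`inst/cli/cvhr-tool.R` (`simulate`, `score`, `cohort` subcommands).

## Documentation

The methods vignette (`vignettes/cvhr-methods.Rmd`) describes the scoring
model, every tunable threshold with its default and rationale, what the
synthetic generator does and does not emulate, and the package's known
limitations.
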