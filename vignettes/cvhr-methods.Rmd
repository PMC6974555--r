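---
title: "Scoring nocturnal heart-rate tachograms for sleep-disordered breathing and autonomic failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nocturnal heart-rate tachograms for sleep-disordered breathing and autonomic failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvhr)
```

## The problem

Obstructive and central sleep apnea produce a stereotyped cardiovascular
signature: during each apnea the heart rate falls, and the terminating
arousal drives a brief tachycardic surge.  Over a night this appears as
*cyclic variation of heart rate* (CVHR) in the instantaneous-HR tachogram,
with a typical cycle length of 30–60 s.  Because Holter ECGs are routine
in post-myocardial-infarction care, CVHR is a convenient, equipment-free
surrogate screen for sleep-disordered breathing (SDB).

Two per-patient phenotypes matter downstream:

* **CVHR burden** — the minutes of the night covered by CVHR episodes;
  with a 6-h nocturnal window, SDB is assumed at ≥ 72 min (20 % of the
  segment).
* **The flat tachogram** — a night with almost no heart-rate modulation at
  all.  Such patients cannot be scored for SDB, and the flatness itself
  indicates severely impaired autonomic control of heart rate; the
  package keeps this group strictly separate (`indeterminate_flat`)
  rather than forcing it into the present/absent dichotomy.

The cohort stage links these phenotypes, together with the classical
heart-rate-variability (HRV) panel, heart-rate turbulence (HRT),
deceleration capacity (DC) and the severe-autonomic-failure composite
(SAF), to 5-year all-cause mortality.

## Per-patient scoring model

### From beats to tachogram

Input is a beat-annotated RR series: one row per beat with the time of the
beat, the RR interval ending at it (ms), and a label (`N` sinus, `V`
ventricular ectopic, `S` supraventricular, `X` artifact).  The nocturnal
window is 00:00–06:00 wall clock, half-open so the boundary beat is never
counted twice; recordings crossing midnight are handled modularly and a
beat belongs to the window by its *end* time.  A window covered less than
80 % by analyzable beat time is flagged non-analyzable.  Manual scoring
tolerates noise ad hoc, but an automated pipeline needs a stated minimum;
0.8 is this package's choice — high enough that 6-h summaries (SDANN,
CVHR minutes) remain comparable across patients, low enough to tolerate
realistic electrode noise.  It is a `nocturnal_window()` parameter.

Only normal-to-normal (NN) intervals — both bounding beats sinus — enter
the tachogram; gaps left by ectopy remain as discontinuities and are never
interpolated.  The instantaneous heart rate is `60000 / rr_ms`.  Two
derived channels are computed on an evenly resampled 2-Hz grid:

* `hr_smooth_bpm`: a running median (default 5 s).  The median suppresses
  single-beat outliers that survive NN filtering while passing the ≥ 10-s
  arousal plateaus essentially intact; 5 s sits comfortably between those
  two scales.
* `rsa_amplitude_bpm`: respiratory sinus arrhythmia amplitude, estimated
  by band-passing the *unsmoothed* resampled HR in the respiratory band
  (0.15–0.40 Hz, 2nd-order Butterworth, zero-phase) and converting the
  30-s rolling RMS to a sinusoidal amplitude (× √2).

### Flat classification

The flat rule is stated visually in the field: no HR changes ≥ 5 bpm, no
visible RSA.  Automating it requires two quantifications that are this
package's own:

* the excursion is the 0.5th-to-99.5th percentile range of the smoothed
  channel, not the raw min–max, so that one artifact-adjacent beat cannot
  veto flatness — this robustness stands in for the two-physician
  consensus review of the manual procedure;
* "visible RSA" is an RSA amplitude ≥ 1 bpm.  A 1-bpm peak sinusoid is
  about the smallest modulation a reader reliably sees on a compressed
  nocturnal tachogram; the threshold is configurable
  (`classify_flat(rsa_min_bpm = )`).

Both thresholds interact safely with CVHR scoring: a detectable arousal
rises ≥ 6 bpm, so no tachogram containing one can be flat (6 > 5).

### CVHR scoring

An **arousal** is a maximal span where the smoothed HR exceeds the local
baseline by ≥ 6 bpm for ≥ 10 s.  The manual method never defines the
reference level, so the package must: the baseline is the running lower
quartile of the smoothed HR over a centered 120-s window.  The lower
quartile tracks the bradycardic troughs between arousals — the natural
reference for "HR increase" in a cyclic pattern — without being dragged
upward by the surges themselves (within one 45-s cycle the surge occupies
well under half the window).  An ordinary running mean or median would sit
partway up the surges and systematically understate their amplitude.

**Episodes** chain ≥ 3 successive arousals with gaps (end of one to start
of the next) ≤ 120 s; shorter chains are discarded.  An episode spans
first-arousal onset to last-arousal end, so the apneic bradycardia phases
between arousals count as CVHR time, and total CVHR duration is the sum of
episode spans in continuous (not whole) minutes.  All thresholds are
inclusive (≥ 6 bpm, ≥ 10 s, ≤ 120 s, ≥ 3 arousals, ≥ 72 min), mirroring
the rule's ≥/≤ wording, and every one is a configuration key
(`pipeline_config()$cvhr`).

### Risk-marker panel

Time-domain HRV follows the standard definitions: SDNN (SD of all NN),
SDANN (SD of 5-min segment means; at least two segments each with ≥ 50 %
NN coverage, otherwise `NA`), RMSSD (within contiguous NN runs only), and
the triangular index with the conventional 1/128-s histogram bin.
Frequency-domain powers use cubic resampling of the NN tachogram at 4 Hz,
removal of a ~0.003-Hz running-mean trend, and Welch's method (300-s Hann
segments, 50 % overlap); bands are VLF 0.0033–0.04, LF 0.04–0.15, HF
0.15–0.40 Hz, with total power their sum, and stretches separated by gaps
> 20 s are analyzed separately and averaged by duration.  Band edges and
bin width follow the established task-force conventions.  The panel is
computed over the full recording by default, with a nocturnal-only mode
(`pipeline_config(hrv = list(segment = "nocturnal"))`); practice varies
on which segment such panels use, both are defensible, and the flag makes
the choice explicit.

HRT uses the standard VPC filter (coupling < 80 % and pause > 120 % of the
local reference NN, context NN within 300–2000 ms, ≥ 2 NN before and 15
after), TO as the percentage change of the two post- versus two pre-VPC NN
intervals averaged over VPCs, and TS as the steepest 5-interval regression
slope of the VPC-averaged post-pause tachogram (averaging before slope
fitting, the standard convention).  DC uses phase-rectified signal
averaging with anchors prolonged by < 5 %, 20-beat windows, and
`DC = (X(0) + X(1) − X(−1) − X(−2)) / 4`; at least 100 anchors are
required.  Patients without a valid VPC (or too few anchors) get `NA`
markers and drop out of the SAF denominator — defaulting them to
"normal" would bias the SAF group.
SAF is the conjunction of abnormal HRT (TS ≤ 2.5 ms/RR **and** TO ≥ 0 %)
and abnormal DC (≤ 4.5 ms).

## Survival stage

Kaplan–Meier curves carry Greenwood variances with the confidence interval
on the log(−log S) scale, the common conservative choice, which keeps
bands inside [0, 1].
Cox models maximize the Efron partial likelihood (death times in such
cohorts are near-continuous, so the tie method is almost immaterial, but
Efron is the better approximation when ties do occur) with Wald intervals.
The exploratory threshold scan evaluates, for every observed CVHR value
(or a supplied grid), the KM 5-year mortality of the subgroup with CVHR
≤ threshold, suppressing subgroups under 20 patients — small-subgroup
estimates at the extreme left of the scan would otherwise be dominated by
a handful of deaths.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every stage is validated.

`simulate_tachogram()` builds instantaneous HR as base rate + slow drift
(sinusoid spanning at most an hour) + RSA sinusoid (~0.25 Hz) + planted
episode waveforms + white beat-level noise, then lays beats sequentially
(`RR = 60/HR`), so the RR/time consistency invariant holds by
construction.  Each episode cycle dips by half the surge amplitude
("apnea") and then surges above baseline for the arousal; planted episodes
satisfy the CVHR rules by construction (≥ 3 cycles, surges ≥ 6 bpm and
≥ 10 s, gaps ≤ 120 s), and the ground truth (surge-train spans, flat flag)
travels with the series.  Flat mode forces zero RSA, no episodes, and
drift under 5 bpm.

`simulate_cohort()` draws covariates from baseline distributions typical
of a large post-MI cohort (age median 59.2, IQR 51.6–66.8 years; LVEF 55, 45–63 %;
GRACE 96, 80–113 points; 20.6 % female; 17 % diabetes) as truncated
normals from median/IQR; nocturnal respiratory rate is lognormal with median 16.5 breaths/min — a realistic
nocturnal post-MI value — and serves only as a correlation-target
covariate.  Flat status (4.8 % marginal prevalence) is linked to age by a
logistic model (0.065 log-odds per year, matching the ~8-year age shift of
the flat group) whose intercept is calibrated against the drawn ages.
CVHR minutes come from a two-component mixture — a gamma low mode
(shape 1.5, scale 18, truncated below 72) that populates the ≤ 19-min
high-risk tail, and a normal high mode (115 ± 30, truncated to [72, 360])
— with 38.6 % weight on the high mode.  Outcomes follow an exponential
proportional-hazards model whose default generating coefficients are
multivariable hazard ratios of the kind reported in large post-MI cohorts (flat 1.73, age 1.06/y, female 0.98, LVEF
0.95/%, GRACE 1.004/pt, diabetes 1.66), administrative censoring at 5
years, and a baseline rate calibrated so the marginal 5-year event
fraction is 0.1035 (the value implied by the default group mortalities of
29.1 % in the flat and 9.4 % in the non-flat stratum).
An exponential baseline is the simplest hazard consistent with the
proportional-hazards analyses the cohort stage performs; nothing
downstream depends on the baseline's shape.

What the generator does **not** emulate: real apnea physiology
(periodicity jitter, amplitude drift, position effects), non-stationary
noise and electrode artifacts, atrial fibrillation, correlated covariates
beyond the age–flat link, and informative censoring.  Passing tests
therefore demonstrate that the implementation applies its stated rules
correctly and recovers known truth under clean conditions — not that the
detector's operating characteristics transfer to arbitrary clinical
recordings.

## Numerical choices and degenerate inputs

* Resampling: 2 Hz for the CVHR chain (cycles of interest are ≥ 10 s),
  4 Hz for spectra (HF band must be clear of Nyquist); linear
  interpolation for HR (robust at gaps), cubic for the spectral tachogram.
* The RSA rolling-mean envelope is clamped at zero before the square root
  (floating cancellation can produce −1e−18).
* Running baselines shrink their windows at recording edges rather than
  padding.
* Ties/boundaries: every scoring threshold is inclusive; subsetting in
  the threshold scan is `≤ τ`.
* Degenerate inputs fail loudly and specifically: empty files,
  non-monotone times, non-positive RR and unknown labels are rejected
  with the offending row; fewer than two N beats warns and returns an
  empty NN series; constant NN series give DC `NA` (no anchors) and
  near-zero total power; Cox fits refuse constant covariates, fewer
  events than covariates, and unconverged solutions.

## Problem sizes

The test suite validates the detector on fifty 1-h seeded recordings
(three 6-cycle episodes each), the flat classifier on 200 boundary-
spanning 15-min fixtures, Wald-interval coverage on 500 replicate Cox fits
of n = 300, and the calibrated-recovery checks on 50 cohorts of n = 1590
(hazard-ratio recovery) plus 100 groups per arm (mortality recovery).  The
acceptance script uses 200 replicates throughout.  These sizes give
Monte-Carlo standard errors comfortably below the corresponding
tolerances: e.g. the mean flat-tachogram hazard ratio over 50 cohorts has
a standard error of ~0.06 against a ±0.15 tolerance.  Note that the mean
of replicate hazard-*ratio* estimates sits slightly above the generating
value (Jensen: `E[exp(β̂)] ≈ exp(β + σ²/2)`, here ≈ 1.78 for a generating
1.73); the recovery tolerances accommodate this known, expected bias.

## Limitations

* CVHR cannot distinguish obstructive from central apnea, and the scoring
  reproduces a surrogate screen, not polysomnography.
* The automated baseline and RSA quantifications are deterministic
  stand-ins for expert visual review; on real data their agreement with
  human scorers should be established before substituting one for the
  other.
* HRT is undefined in patients without qualifying VPCs; cohort-level SAF
  statistics are conditional on HRT/DC being defined.
* The nocturnal respiratory rate is an input covariate here; its
  derivation from the ECG is out of scope.
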