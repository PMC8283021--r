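---
title: "Methods: cardiorespiratory and sleep phenotyping in cardioresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory and sleep phenotyping in cardioresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cardioresp` implements the complete analysis chain of a murine
cardiorespiratory phenotyping study — blood-pressure telemetry, spectral
heart-rate variability, whole-body plethysmography, the hypoxic ventilatory
response, EEG/EMG sleep staging and sleep-disordered-breathing scoring —
together with a synthetic-signal generator that emulates the whole study
design with known ground truth. This vignette documents the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and what the synthetic validation does and does not establish.

## The synthetic study and its presets

No raw recordings accompany the study this pipeline targets, so every
analysis stage is validated against simulated cohorts whose parameters are
the group values the study reports. A preset (`synth_preset()`) collects
them; two are shipped:

* `preset_nzo_baseline()` — the untreated hypertensive-obese condition:
  light/dark-phase MAP 134.9/137.5 mmHg; total sleep time 54.2% of a 6-h
  light-phase recording with 88.5% of sleep as NREM (about 22 min of REM);
  NREM breathing with tidal volume 0.3 mL at 107.5 breaths/min and
  inspiratory duty cycle 0.3; apneas at 31.4 and desaturations at 8.4
  events per hour of sleep; normoxic and hypoxic ventilation 1.2 and
  2.9 mL/min/g; body weight 45.6 g.
* `preset_alloaca_treated()` — the leptin-receptor-blocker-treated
  condition: light/dark MAP 124.9/127.9 mmHg, body weight 42.4 g, hypoxic
  ventilation 3.0 mL/min/g, all else shared.

Values the study does not print were fixed once, as follows, and are not
tuned thereafter:

* **SBP/DBP levels.** Only MAP is reported, so presets carry a target MAP
  per phase plus a pulse pressure of 40 mmHg (typical of murine femoral
  telemetry); SBP/DBP follow from the one-third pulse-pressure rule.
* **Between-animal variance.** The MAP offset SD is 7 mmHg, chosen so a
  five-animal group reproduces the reported SEMs of 3.1–5.7 mmHg.
* **Hypoxic SpO~2~.** Saturation falls from 97% to 63%; with the printed
  ventilation pair this makes the true HVR slope exactly
  (2.9 − 1.2)/(97 − 63) = 0.05 mL/min/g per %SpO~2~.
* **Channel noise.** Additive Gaussian noise per channel (1 mmHg pressure,
  2 bpm heart rate, 0.02 mL/s airflow, 15 µV EEG, 0.15% SpO~2~). The
  airflow value is set so that a breath scaled to 5% amplitude during an
  apnea still measures at or below 10% of the local baseline after noise —
  the generator's ground-truth contract with the apnea detector.

All randomness flows from one seeded generator per call; the same preset
and seed give bit-identical signals.

### Signal models

* **Arterial pressure** is a per-beat raised cosine between DBP and SBP at
  the preset heart rate, with a 12-h-period sinusoidal circadian component
  (amplitude 5 mmHg) superimposed within each lighting phase. Because that
  component has zero mean within each phase, the phase means equal the
  preset targets exactly, which is what makes the telemetry
  parameter-recovery test well-posed.
* **Airflow** is built breath by breath: a half-sine inspiration over
  `Ti = DC × Ttot` whose amplitude is set by the tidal volume
  (`A = πV_T / 2Ti`), and a volume-balancing half-sine expiration.
  Flow-limited breaths are amplitude-clipped at 60% of the unclipped peak
  over 20–80% of `Ti` and carry a rising effort envelope; apneas replace
  3–5 whole consecutive breath cycles with 5%-amplitude copies, so every
  inserted event satisfies the ≥90%-reduction / ≥0.7-s scoring rule by
  construction and its duration is exactly recoverable.
* **EEG/EMG** are generated per 10-s epoch from the hypnogram: NREM epochs
  carry high-amplitude 3.5 Hz activity, REM low-amplitude 7 Hz activity,
  WAKE mixed 8 Hz; EMG is white noise with stage-dependent amplitude
  (atonia in REM). The hypnogram itself alternates WAKE → NREM (→ REM with
  a branching probability) bouts with geometric lengths whose means are
  chosen so the expected stage fractions match the preset.
* **SpO~2~** sits at a 97% baseline with piecewise-linear desaturation
  dips (descent 30%, plateau 40%, recovery 30% of a 20–60 s duration) of
  the preset depth, inserted during sleep.

Events are inserted a couple of breaths clear of stage-bout boundaries so
that detected onsets remain attributable to sleep under the
stage-at-onset convention; this is part of the generator's recoverability
contract, not a property claimed for real data.

## Blood-pressure telemetry

`detect_beats()` compares the lightly smoothed waveform against a 1-s
rolling mean and opens one cardiac cycle per upward crossing, with a
refractory period of 60/800 s so no rhythm faster than 800 bpm is
admitted; SBP/DBP are the raw per-cycle extremes. `hourly_summary()`
averages beats into clock-aligned hourly bins and derives
`MAP = DBP + (SBP − DBP)/3`. The study states that MAP was *calculated*
from hourly SBP/DBP without giving the formula; the one-third
pulse-pressure rule is the standard choice and is applied to the hourly
means. (On the raised-cosine waveform model the time-averaged pressure
would differ from this formula; the package consistently defines both the
generator's ground truth and the analyzer's output through SBP/DBP, so the
recovery comparison is internally exact.) Hours are assigned to the light
phase when the clock hour lies in `[lights_on, lights_on + 12)`, lights on
at 9 by default. Hours without beats are kept as missing rows and excluded
from phase means.

## Heart-rate variability

The pipeline follows the study's procedure literally: readings strictly
below 200 or above 800 bpm are artifacts, imputed by linear interpolation
(nearest valid value at the edges); the beat-to-beat interval is `60/HR`;
the interval series is cut into 2-min segments overlapping by 1 min,
mean-removed, Hamming-windowed and Fourier-transformed; LF is the
0.4–1.5 Hz power, HF the 1.6–4.0 Hz power, and LF/HF their ratio. Band
powers are averaged across segments first and the ratio is taken on the
averages ("ratio of averages"), matching the study's segment-averaging
step; the alternative (average of ratios) is noisier and was not described.

Two numerical choices deserve note:

* **0.1 Hz resolution by aggregation.** Two-minute windows give a native
  resolution of 1/120 Hz; the stated 0.1 Hz resolution is implemented as
  post-hoc aggregation of raw periodogram bins onto a 0.1 Hz grid. The
  bins are *centered* on grid frequencies (`[k·0.1 ± 0.05)`): a modulation
  at a grid frequency then falls mid-bin and keeps ≥97% of its Hamming
  main lobe in one bin, and band membership resolves naturally by bin
  center, inclusive at both edges — a 1.5 Hz peak is LF, a 1.6 Hz peak is
  HF. Edge-aligned bins would split an on-grid peak across two bins.
* **Scaling.** One-sided power is normalized as `2|X_k|²/(N·Σw²)`, so the
  binned total equals the window-compensated signal variance and binning
  conserves total power exactly (Parseval; unit-tested). Interval power is
  reported in ms² (1 s² = 10⁶ ms²).

The interval series is analyzed as a uniformly sampled signal (the input
is an instantaneous-HR channel) and downsampled to 20 Hz — Nyquist 10 Hz,
comfortably above the 4 Hz band ceiling — for speed.

## Breath-by-breath analysis

`segment_breaths()` finds breath onsets at negative-to-positive zero
crossings of the smoothed flow with a hysteresis of 2% of the running
amplitude (95th percentile of |flow|), which suppresses noise-triggered
micro-breaths. Per breath: `Ti` is the positive-lobe duration, `V_T` the
integral of raw flow over it, `V_Imax` the smoothed-peak flow (smoothing
prevents single noise samples from inflating the amplitude of near-silent
breaths), `MIFR = V_T/Ti`, `DC = Ti/Ttot`, and instantaneous
`V_E = V_T·60/Ttot`. Cycles outside 0.1–2 s (30–600 breaths/min) are
rejected as artifacts. Minute ventilation is the mean instantaneous `V_E`
over breaths, normalized by body weight.

Inspiratory flow limitation has no numeric definition in the source, only
a qualitative one (early inspiratory plateau with rising effort). The
package operationalizes it as: (a) flow reaches 95% of `V_Imax` within the
first 40% of `Ti`; (b) flow stays within 5% of that plateau for a
*contiguous* run of at least 40% of `Ti`; (c) mean effort over the second
half of the plateau exceeds the first half by at least 5%. All thresholds
sit in `cr_config()`. The contiguity requirement in (b) is what rejects an
unclipped half-sine breath (its within-5% run lasts only ~20% of `Ti`,
and it reaches 95% of peak only at ~40% of `Ti`, borderline under (a));
these thresholds are validated only against synthetic clipped breaths, not
against scorer judgment on real traces.

## Hypoxic ventilatory response

`split_challenge()` fixes the analysis windows: the normoxic reference is
the final 5 min of the 20-min normoxic period (post-acclimation, quiet;
the study does not state its averaging window, so this default is an
assumption and is configurable), and the hypoxic window runs from 30 s to
2 min after the switch, the 90-s early sustained response the study
analyzes. `compute_hvr()` pairs each breath's instantaneous `V_E` with the
nearest SpO~2~ sample and fits ordinary least squares of `V_E` (mL/min) on
SpO~2~ (%) over the pooled breath-level points of both windows; the HVR is
the sign-flipped slope over body weight, positive when ventilation rises
as saturation falls. For two clusters of equal weight this equals the
two-point slope between window means (`method = "two_point"` makes that
explicit), so the pooled-vs-means ambiguity in the source is immaterial
for the recovery targets.

## Sleep staging and event scoring

`score_epochs()` turns the study's visual criteria into a deterministic
rule on 10-s epochs: EEG band powers at 2–5 Hz and 5–10 Hz (periodogram
sums) plus EMG RMS. An epoch is REM when 5–10 Hz power dominates by a
factor 1.5 under atonia, NREM when 2–5 Hz dominates by 1.5 under low
tonus, WAKE otherwise. The two EMG thresholds are calibrated per recording
from its own log-RMS distribution (tonus threshold at the geometric
mid-quartile point; atonia threshold between the 1st and 35th
percentiles), with explicit overrides available. This is a faithful
operationalization of the stated criteria, not a claim of equivalence with
a human scorer; on clean synthetic signals it recovers the generating
hypnogram at ≥99% of epochs, which bounds pipeline error, not scorer
agreement on real EEG.

Architecture follows the printed definitions: TST = NREM + REM time, stage
percentages of TST, efficiency = TST / recording duration. The printed
efficiencies in the source imply per-animal recording durations somewhat
below the nominal 6 h; the package keeps the definitional form.
`select_analysis_windows()` returns every REM run and, per 30-min block,
one 20-s window at the first run of ≥2 consecutive NREM epochs,
automating the study's manual NREM subsampling.

**Apneas.** A rolling baseline (median `V_Imax` of the preceding 10
breaths) tracks normal breathing; a run of breaths at ≤10% of baseline
(≥90% reduction) is scored as an apnea when it lasts ≥0.7 s *or* spans two
local breath cycles (twice the median recent `Ttot`) — the source's "two
breath cycles or ≥0.7 s" read as a disjunction. The event start is backed
up from the (hysteresis-delayed) crossing to the true zero crossing so a
0.7-s reduction measures as 0.7 s; durations are compared with a
one-sample quantization allowance. Events with onset in WAKE epochs are
discarded; the apnea index divides the count by TST. The source's Table
lists apneas under REM while defining the index over total sleep time; the
package scores over all sleep and also reports stage at onset so either
stratification can be formed.

**Desaturations.** The SpO~2~ baseline is a trailing 60-s rolling median
(the channel is decimated to ≤5 Hz first; desaturations evolve over tens
of seconds, so this is lossless for scoring). An event opens at a drop of
≥5 points from baseline and closes on recovery to within 2 points; both
the baseline window and the recovery hysteresis are package assumptions
held in `cr_config()`. ODI divides the count by TST; mean SpO~2~ is
reported separately over NREM and REM epochs.

## Statistics and reporting

`mann_whitney_u()` and `wilcoxon_signed_rank()` wrap `stats::wilcox.test`:
exact null distributions for small samples without ties (min group size
≤8; ≤12 nonzero differences), normal approximation with tie and continuity
corrections otherwise; two-sided throughout. The test suite verifies the
exact branch against brute-force enumeration (all rank assignments; all
2^n sign patterns). Cohen's d is the mean difference over the pooled SD.
`study_report()` assembles per-animal tables into group mean ± SEM with
between-group Mann–Whitney p-values and reports absent sections as
explicit gaps; mixed-effects modelling is deliberately left to external
tools, with per-animal rows formatted for export.

## Problem sizes and reproduction

The generators default to the acquisition rates of the emulated hardware
(400 Hz pressure, 1000 Hz airflow/EEG/EMG, 100 Hz HR/SpO~2~). The test
suite, the analysis scripts and `scripts/acceptance.R` generate at reduced
rates chosen as the package's working problem sizes — 100 Hz pressure,
200 Hz airflow, 100 Hz EEG/EMG, 5 Hz SpO~2~ — after checking analytically
that the induced biases are negligible against the recovery tolerances
(e.g. peak sampling of a 600-bpm raised-cosine pulse at 100 Hz biases MAP
by <0.15 mmHg; 200 Hz airflow resolves a 0.17-s inspiration with ~34
samples). `scripts/acceptance.R` regenerates the full validation — a
five-animal 48-h telemetry cohort per arm target, one hypoxic challenge,
one 6-h polysomnogram — from a single command-line seed and writes the
recovered quantities as JSON.

## Limitations

The synthetic signals are clean by design: stage transitions aligned to
epoch boundaries, stationary within-stage breathing, no movement artifacts,
no electrode drift, sinusoidal EEG rather than 1/f backgrounds. Passing
recovery tests therefore demonstrates correctness of the implemented
rules and estimators, not robustness to real-world recordings. Beat
detection assumes the pulse morphology of the generator; real arterial
waveforms with dicrotic notches may need the prominence parameters
adjusted. WBP volume calibration (chamber constants, humidity/temperature
corrections) is out of scope — airflow is assumed pre-calibrated to mL/s.
Hypopnea scoring, arousal detection and human AASM rules are intentionally
absent.
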