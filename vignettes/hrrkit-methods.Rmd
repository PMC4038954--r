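---
title: "Methods: heart rate recovery and RR spectral analysis in hrrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart rate recovery and RR spectral analysis in hrrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrrkit)
```

## The problem

After a symptom-limited exercise test, heart rate falls back towards rest
through sympathetic withdrawal and parasympathetic reactivation. The speed of
that fall — heart rate recovery (HRR) — is a marker of autonomic function and
a prognostic indicator in cardiovascular disease, and is blunted in
hypertrophic cardiomyopathy (HC), particularly with left ventricular outflow
tract obstruction. hrrkit implements the full analysis chain for such
studies: beat times in, per-subject recovery statistics and recovery-phase
RR spectra out, plus the cohort-level statistics used to compare groups and
model predictors of recovery.

## Heart rate recovery metrics

All analyses start from a `beat_series`: one timestamp per heartbeat,
labelled `rest`, `exercise` or `recovery`, with the recovery origin defined
as the moment the workload returns to zero. The heart rate "at" a time point
is the mean of 60000/RR over **10 consecutive accepted RR intervals** around
that point. The window is centred — five intervals ending before the target
time, five starting at or after it, shifted inward at recording edges.
Whether the convention behind the published definition was centred or
backward-looking is unstated; the centred choice is ours, made for symmetry,
and is recorded here rather than attributed.

Per subject, at t = 60, 120, 180 s of recovery, three normalisations are
computed:

* absolute: `HRR(t) = HR_peak − HR(t)` (beats/min),
* as a fraction of peak HR: `100 · HRR(t) / HR_peak` (%),
* as a fraction of heart-rate reserve: `100 · HRR(t) / (HR_peak − HR_rest)` (%).

Resting HR is the 10-beat mean at the midpoint of the rest phase; peak HR is
the maximum 10-interval rolling mean over the exercise phase. Negative
recovery values (HR above peak during recovery) are retained with a warning
rather than clipped, so QC can see them. A rise in systolic blood pressure
of strictly less than 20 mm Hg from rest to peak is classified as an
abnormal blood pressure response; a rise of exactly 20 is normal.

## Artifact handling

The recording technique (finger plethysmography) is known to introduce noise
and to misrepresent ectopy, but no cleaning rule comes with the study design,
so hrrkit uses common HRV practice: an RR interval is rejected when outside
[300, 2000] ms or when it differs from the previous accepted interval by more
than 20%. Rejected samples are **interpolated** for spectral analysis (the
estimators need a gap-free series) but **deleted** from windowed HR means
(a mean must not be biased by synthetic samples). Rejecting more than 20% of
a segment flags the result rather than aborting it.

## Spectral analysis of the recovery tachogram

Power spectra are estimated on the first 180 s of recovery by three methods,
runnable side by side:

* **Welch**: mean and linear trend removed, 60-s Hann segments with 50%
  overlap, one-sided density scaled by the window power so the PSD
  integrates to the detrended variance (Parseval). 60-s segments are the
  longest that still give three averages from a 180-s record.
* **Autoregressive**: Yule–Walker via the Levinson–Durbin recursion on the
  biased autocovariance, default order 16 (a common HRV choice; the order is
  configurable and was not prescribed).
* **Lomb–Scargle**: the classical periodogram evaluated directly on the
  unevenly sampled RR series — that is its purpose, so no resampling is done
  for it. The raw periodogram is converted to a one-sided density by
  `2 · span / n`, which makes the main lobe of a pure sinusoid of amplitude
  A integrate to A²/2. Uneven sampling scatters a leakage floor across the
  grid; with beat-like (jittered) sampling this floor is small, but for
  sparse irregular sampling it inflates band powers — a property of the
  estimator, not a bug, and the reason the tone-recovery tests sample at
  beat-like times.

Welch and AR operate on the artifact-interpolated series resampled to 4 Hz
by cubic spline (convention; configurable). Band powers are trapezoidal
integrals over VLF 0.0033–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz (Task Force
edges; the study names the bands but not the edges). Normalised units divide
LF and HF by total power minus VLF, so `lf_nu + hf_nu = 1` holds exactly and
values are fractions in [0, 1], matching the convention in which the
published table prints them (0.56/0.44). An HF power of zero makes the LF:HF
ratio missing, never infinite. The linear detrend is the minimal fix for the
nonstationarity of a decaying recovery record; residual very-low-frequency
trend ends up in the VLF band, which is excluded from the normalised units
for exactly that reason.

## The synthetic cohort generator

No beat-level data are deposited with the study, so the generator emulates
the stated world at the group level and is itself first-class, tested code.
Each subject draws kinetics from group distributions: resting HR, peak HR
(group means/SDs from the published baseline table), a recovery asymptote
(plateau) and a mono-exponential time constant τ. The instantaneous HR
profile is rest (constant) → exercise (linear ramp) → recovery
`plateau + (peak − plateau)·exp(−t/τ)`, continuous at the boundaries.

The RR function is `60000 / HR(t)` plus sinusoidal LF (0.10 Hz) and HF
(0.25 Hz) modulation applied additively in the RR domain — HRV amplitudes
are conventionally in ms — then inverted to a rate and fed to an **IPFM**
(integral pulse frequency modulation) sampler: a beat fires each time the
integral of the rate crosses an integer. White RR noise is added per
interval afterwards. Optional ectopy displaces random beats to a 40–60%
coupling interval, leaving the next beat in place so the compensatory pause
emerges naturally.

Choices where the study gives no individual-level values:

* **Plateau and τ** are calibrated by least squares so each group's mean
  recovery curve passes through the published group-mean HR at 1, 2 and
  3 min: control 105.7 bpm / 86.5 s, nonobstructive 100.8 / 74.6,
  obstructive 114.1 / 60.0. A biexponential model is left as a config
  extension; the mono-exponential matches the published mean curve shape.
* **Modulation amplitudes** default to 22 ms (LF) and 20 ms (HF) with 15 ms
  white RR noise, giving normalised LF around 0.5 — the magnitude the
  published table reports — at realistic total power for early recovery.
* **Phase durations** default to 180 s rest, 360 s exercise ramp and 200 s
  recovery; recovery must be at least 180 s because the spectra consume
  3 minutes of continuous recovery RR data.
* Echo measurements for controls are plausible normal-heart values (they are
  never used by the disease-severity model); LVOT gradients are lognormal,
  matched to the published medians and interquartile ranges per subgroup.

What a green test on this generator establishes: the pipeline recovers known
kinetics, band powers and planted regression structure from data with the
assumed statistical shape. What it does not establish: behaviour under real
plethysmography artifacts, respiration-coupled HF drift, atrial
fibrillation, or non-exponential recovery — none of which are modelled.

## Cohort statistics

Summary style and test family are gated by Shapiro–Wilk at α = 0.05
(mean ± SD with t/ANOVA when normal, median [IQR] with rank tests
otherwise). Group comparisons use the pooled-variance independent t-test,
one-way ANOVA with all-pairs Bonferroni post hoc (multiplier = number of
pairs, capped at 1), Fisher's exact test (authored as the two-sided
hypergeometric tail sum), and Mann–Whitney/Kruskal–Wallis with exact
enumeration for small tie-free samples and the tie-corrected normal
approximation otherwise.

Two regression models mirror the published analysis:

* **Model 1** (pooled controls + patients): backward elimination over
  {HC diagnosis, sex, age, peak HR, BMI, peak VO₂} for HR at 1, 2 and 3 min.
  The elimination rule — refit, drop the least significant non-forced
  covariate at p ≥ 0.05, repeat — was not stated explicitly and is recorded
  as our choice, as is not forcing age/BMI.
* **Model 2** (patients only): univariable screen of five disease-severity
  surrogates (lateral E/E′, left atrial size, ejection fraction, maximal
  wall thickness, peak LVOT gradient), then a multivariable fit of the
  screen passers with the Model-1 adjustment covariates (peak HR, sex)
  forced in. The published methods mention left atrial *area* while the
  table records *diameter*; the covariate is a single configurable column
  `la_size`, defaulting to the diameter.

Subjects with a missing response or covariate are excluded listwise per
response. Submaximal tests (respiratory exchange ratio < 1.05) and athletic
controls are excluded upstream with machine-readable reasons.

## Numerical notes and limitations

* IPFM integrates the rate by trapezoid on a 10-ms grid and locates
  threshold crossings by inverse linear interpolation; a constant rate
  yields exactly periodic beats, and beat counts match the rate integral
  within one beat on any window.
* The rolling-mean peak HR is biased low by about half the ramp slope times
  the window span (~0.5 beats/min at a realistic 0.3 beats/min/s ramp);
  tests account for this rather than hiding it.
* Heart-rate reserve below 1e-6 beats/min is treated as undefined (guards
  the constant-HR degenerate case against floating-point ties).
* JSON (not YAML) is the config format: no YAML parser is part of the
  package's dependency footprint.
* The known internal inconsistency in the published table — the all-HC
  2-minute reduction prints 36.8 while peak minus 2-min HR gives 36.2 — is
  documented and excluded from arithmetic targets; all other printed
  reductions are reproduced exactly by the identity checks.
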