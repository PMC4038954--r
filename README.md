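# hrrkit

Heart rate recovery (HRR) and RR-interval spectral analysis for exercise
testing, with a cohort statistics layer and a seeded synthetic cohort
generator.

## What it is for

After a symptom-limited exercise test, heart rate decays back towards rest
through vagal reactivation and sympathetic withdrawal. How fast it decays —
and how the beat-to-beat RR spectrum is partitioned between low-frequency
(LF, 0.04–0.15 Hz) and high-frequency (HF, 0.15–0.4 Hz) power during
recovery — are markers of autonomic function, blunted in conditions such as
hypertrophic cardiomyopathy (HC). hrrkit takes **beat times** (one timestamp
per heartbeat, labelled rest / exercise / recovery) and computes:

* **HRR metrics** — resting HR, peak HR (10-beat windowed means), and at
  t = 60/120/180 s of recovery the recovery drop `HR_peak − HR(t)` in
  beats/min, as % of peak HR, and as % of heart-rate reserve
  `HR_peak − HR_rest`;
* **recovery spectra** — PSD of the 3-minute recovery tachogram by Welch
  (Hann, 60-s segments, 50% overlap), autoregressive (Levinson–Durbin,
  order 16) and Lomb–Scargle (on the raw uneven samples) estimators, reduced
  to VLF/LF/HF band powers, normalised units `lf_nu = LF/(LF+HF)` and the
  LF:HF ratio;
* **cohort statistics** — Shapiro–Wilk-gated summaries, pooled t-tests,
  ANOVA with Bonferroni post hoc, Fisher's exact test, rank tests, and two
  backward-elimination linear models (pooled demographic model; patient-only
  disease-severity model with forced adjustment covariates);
* **synthetic cohorts** — an integral-pulse-frequency-modulation (IPFM) beat
  simulator driven by piecewise HR profiles (rest → linear ramp →
  mono-exponential recovery) with sinusoidal LF/HF RR modulation, white RR
  noise and optional ectopy, parameterised from published group-level
  means/SDs, so the whole pipeline is testable without recorded data.

## Worked example

```r
library(hrrkit)

cfg <- generator_config(seed = 42)      # 18 controls, 28 nonobstructive, 13 obstructive HC
cohort <- generate_cohort(cfg)

compute_hrr_profile(cohort[[1]])
#> <hrr_metrics> rest 66.2, peak 192.1, reserve 125.9 beats/min
#>   t=60s: HR 132.4 | drop 59.6 bpm | 31.0% of peak | 47.4% of reserve
#>   t=120s: HR 109.5 | drop 82.5 bpm | 43.0% of peak | 65.5% of reserve
#>   t=180s: HR 99.1 | drop 93.0 bpm | 48.4% of peak | 73.8% of reserve

recovery_spectrum(cohort[[1]], "welch")
#> <band_powers> [welch] VLF 67.9 | LF 252.4 | HF 211.7 ms^2 | LF 0.54 n.u. | LF:HF 1.19

res <- run_pipeline(cohort, methods = "welch")
aggregate(cbind(hr_peak, hrr_abs_60, hrr_abs_120, hrr_abs_180) ~ group,
          res$metrics, function(x) round(mean(x), 1))
#>            group hr_peak hrr_abs_60 hrr_abs_120 hrr_abs_180
#> 1        control   184.7       41.4        60.2        69.9
#> 2 nonobstructive   152.7       31.3        42.4        47.0
#> 3    obstructive   162.0       34.5        44.4        48.0

res$comparisons$hrr_abs_60_t        # control vs patients, 1-minute drop
#> <comparison_result> independent t-test: statistic 2.316, p = 0.02419
```

The group pattern mirrors the clinical finding the package is built to
analyse: patients recover more slowly (smaller drops at every time point),
and the pooled model (`res$model1`) retains peak HR and the HC indicator as
predictors of recovery HR when that structure is present in the data.

A command-line wrapper is in `inst/cli/hrr.R`
(`simulate`, `analyze`, `compare`, `spectra` subcommands).

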