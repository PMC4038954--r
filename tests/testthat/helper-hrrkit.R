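# Shared fixtures: all synthetic, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A single-group config with every SD zeroed, so the drawn kinetics equal the
# group means exactly. Short rest/exercise phases keep tests fast; recovery
# keeps the full 200 s the spectral module needs.
fixed_config <- function(rest = 75, peak = 150, plateau = 100, tau = 60,
                         lf_amp = 0, hf_amp = 0, noise = 0, seed = 1,
                         pd = c(rest = 60, exercise = 300, recovery = 200),
                         n = c(control = 1), ectopy = 0) {
  gp <- default_group_params()
  for (g in names(gp)) {
    gp[[g]]$hr_rest_mean <- rest; gp[[g]]$hr_rest_sd <- 0
    gp[[g]]$hr_peak_mean <- peak; gp[[g]]$hr_peak_sd <- 0
    gp[[g]]$hr_plateau_mean <- plateau; gp[[g]]$hr_plateau_sd <- 0
    gp[[g]]$tau_mean <- tau; gp[[g]]$tau_sd <- 0
  }
  generator_config(n_per_group = n, group_params = gp,
                   lf_amp_ms = lf_amp, hf_amp_ms = hf_amp,
                   noise_sd_ms = noise, ectopy_rate = ectopy,
                   phase_durations = pd, seed = seed)
}

# Beat series at an exactly constant rate (bpm) across all three phases.
constant_rate_beats <- function(bpm = 60, pd = c(rest = 60, exercise = 120,
                                                 recovery = 200)) {
  rr <- 60 / bpm
  times <- seq(rr, sum(pd), by = rr)
  t1 <- pd[["rest"]]; t2 <- t1 + pd[["exercise"]]
  phase <- ifelse(times < t1, "rest", ifelse(times < t2, "exercise", "recovery"))
  beat_series(times, phase, recovery_onset = t2)
}

# Uniform tachogram holding a sum of sinusoids plus optional noise.
tone_tachogram <- function(freqs, amps, phases = rep(0, length(freqs)),
                           span = 300, fs = 4, mean_rr = 800, noise_sd = 0) {
  tt <- seq(0, span, by = 1 / fs)
  x <- rep(mean_rr, length(tt))
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * tt + phases[i])
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(tt), 0, noise_sd)
  tachogram(tt, x, uniform = TRUE, sampling_rate = fs)
}
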