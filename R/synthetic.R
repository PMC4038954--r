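#' Default per-group generator parameters
#'
#' Group-level distributions for the synthetic exercise-test cohort. Heart
#' rate kinetics (resting HR, peak HR) and the demographic / clinical columns
#' use published group means and SDs for healthy controls and for
#' nonobstructive and obstructive hypertrophic cardiomyopathy (HC). The
#' recovery asymptote (`hr_plateau`) and time constant (`tau`) of the
#' mono-exponential recovery model are not published at the individual level;
#' they are calibrated by least squares so each group's mean recovery curve
#' passes through the group-mean HR at 1, 2 and 3 minutes (see the methods
#' vignette). Echo measurements for controls are plausible normal-heart
#' values (synthetic choices; controls are never used in disease-severity
#' models).
#'
#' @return A named list (one element per group label) of distribution
#'   parameters, each itself a named list.
#' @export
default_group_params <- function() {
  list(
    control = list(
      hr_rest_mean = 80.5, hr_rest_sd = 14.7,
      hr_peak_mean = 176.8, hr_peak_sd = 18.1,
      hr_plateau_mean = 105.7, hr_plateau_sd = 12,
      tau_mean = 86.5, tau_sd = 15,
      age_mean = 39.7, age_sd = 10.0,
      bmi_mean = 24.1, bmi_sd = 3.0,
      male_prob = 9 / 18,
      map_rest_mean = 90.8, map_rest_sd = 7.5,
      sbp_rest_mean = 120.3, sbp_rest_sd = 10.1,
      sbp_change_mean = 44.2, sbp_change_sd = 8.1,
      vo2_mean = 35.1, vo2_sd = 8.4,
      workload_mean = 206.1, workload_sd = 73.6,
      mwt_mean = 9, mwt_sd = 1,
      ef_mean = 62, ef_sd = 4,
      la_mean = 36, la_sd = 4,
      lvot_meanlog = log(5), lvot_sdlog = 0.4,
      ee_mean = 6, ee_sd = 1.5,
      nsvt_prob = 0, syncope_prob = 0, fh_scd_prob = 0
    ),
    nonobstructive = list(
      hr_rest_mean = 74.6, hr_rest_sd = 15.8,
      hr_peak_mean = 148.3, hr_peak_sd = 24.4,
      hr_plateau_mean = 100.8, hr_plateau_sd = 12,
      tau_mean = 74.6, tau_sd = 15,
      age_mean = 47.5, age_sd = 13.7,
      bmi_mean = 29.9, bmi_sd = 5.4,
      male_prob = 26 / 28,
      map_rest_mean = 94.3, map_rest_sd = 12.3,
      sbp_rest_mean = 127.7, sbp_rest_sd = 16.1,
      sbp_change_mean = 50.2, sbp_change_sd = 10.7,
      vo2_mean = 24.2, vo2_sd = 6.1,
      workload_mean = 152.3, workload_sd = 50.9,
      mwt_mean = 16, mwt_sd = 4,
      ef_mean = 66.4, ef_sd = 8.6,
      la_mean = 44.5, la_sd = 6.3,
      lvot_meanlog = log(6), lvot_sdlog = 0.66,
      ee_mean = 8.5, ee_sd = 3,
      nsvt_prob = 0.25, syncope_prob = 0.15, fh_scd_prob = 0.2
    ),
    obstructive = list(
      hr_rest_mean = 81.1, hr_rest_sd = 10.6,
      hr_peak_mean = 153.0, hr_peak_sd = 14.7,
      hr_plateau_mean = 114.1, hr_plateau_sd = 10,
      tau_mean = 60.0, tau_sd = 15,
      age_mean = 44.9, age_sd = 11.8,
      bmi_mean = 28.9, bmi_sd = 5.3,
      male_prob = 11 / 13,
      map_rest_mean = 89.6, map_rest_sd = 13.4,
      sbp_rest_mean = 118.8, sbp_rest_sd = 22.3,
      sbp_change_mean = 44.0, sbp_change_sd = 15.0,
      vo2_mean = 22.5, vo2_sd = 4.4,
      workload_mean = 123.5, workload_sd = 32.5,
      mwt_mean = 19, mwt_sd = 3.5,
      ef_mean = 68.2, ef_sd = 5.5,
      la_mean = 41.8, la_sd = 5,
      lvot_meanlog = log(78), lvot_sdlog = 0.38,
      ee_mean = 9.5, ee_sd = 3,
      nsvt_prob = 0.25, syncope_prob = 0.15, fh_scd_prob = 0.2
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The stated world of the simulator: per-group heart-rate kinetics, RR-domain
#' oscillatory modulation in the LF and HF bands, white RR noise, optional
#' ectopy, phase durations and a master seed. Defaults emulate a
#' symptom-limited bicycle exercise test followed by 3+ minutes of upright
#' static recovery.
#'
#' @param n_per_group Named integer vector: subjects per group label. Default
#'   is the study's group sizes (18 controls, 28 nonobstructive,
#'   13 obstructive HC).
#' @param group_params Per-group distributions; see [default_group_params()].
#' @param lf_freq,hf_freq Centre frequencies (Hz) of the low- and
#'   high-frequency RR modulation sinusoids.
#' @param lf_amp_ms,hf_amp_ms Modulation amplitudes in ms.
#' @param noise_sd_ms White RR noise SD in ms, added per interval.
#' @param ectopy_rate Ectopic beats per minute (0 disables).
#' @param phase_durations Named numeric vector of `rest`, `exercise`,
#'   `recovery` lengths in seconds; recovery must be >= 180 s because the
#'   spectral analysis consumes 3 minutes of continuous recovery RR data.
#' @param seed Master seed (integer).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_per_group = c(control = 18, nonobstructive = 28,
                                             obstructive = 13),
                             group_params = default_group_params(),
                             lf_freq = 0.10, hf_freq = 0.25,
                             lf_amp_ms = 22, hf_amp_ms = 20,
                             noise_sd_ms = 15,
                             ectopy_rate = 0,
                             phase_durations = c(rest = 180, exercise = 360,
                                                 recovery = 200),
                             seed = 1L) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(group_params))) {
    stop("`n_per_group` must be named with labels present in `group_params`",
         call. = FALSE)
  }
  if (any(n_per_group < 0)) stop("`n_per_group` must be >= 0", call. = FALSE)
  if (!(lf_freq >= 0.04 && lf_freq < 0.15 && hf_freq >= 0.15 && hf_freq <= 0.4)) {
    stop("need 0.04 <= lf_freq < 0.15 <= hf_freq <= 0.4 Hz", call. = FALSE)
  }
  if (lf_amp_ms < 0 || hf_amp_ms < 0 || noise_sd_ms < 0 || ectopy_rate < 0) {
    stop("amplitudes, noise SD and ectopy rate must be >= 0", call. = FALSE)
  }
  pd <- phase_durations[c("rest", "exercise", "recovery")]
  if (any(is.na(pd)) || any(pd <= 0)) {
    stop("`phase_durations` needs positive rest, exercise, recovery entries",
         call. = FALSE)
  }
  if (pd[["recovery"]] < 180) {
    stop("recovery duration must be >= 180 s (3 minutes are analysed)",
         call. = FALSE)
  }
  for (g in groups) {
    p <- group_params[[g]]
    sds <- grep("_sd$|_sdlog$", names(p), value = TRUE)
    if (any(unlist(p[sds]) < 0)) {
      stop(sprintf("group '%s': SDs must be >= 0", g), call. = FALSE)
    }
    if (p$hr_rest_mean >= p$hr_peak_mean) {
      stop(sprintf("group '%s': hr_rest_mean must be < hr_peak_mean", g),
           call. = FALSE)
    }
    if (p$hr_plateau_mean > p$hr_peak_mean) {
      stop(sprintf("group '%s': hr_plateau_mean must be <= hr_peak_mean", g),
           call. = FALSE)
    }
    if (p$tau_mean <= 0) stop(sprintf("group '%s': tau must be > 0", g), call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, group_params = group_params,
                 lf_freq = lf_freq, hf_freq = hf_freq,
                 lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
                 noise_sd_ms = noise_sd_ms, ectopy_rate = ectopy_rate,
                 phase_durations = pd, seed = as.integer(seed)),
            class = "generator_config")
}

#' Integral pulse frequency modulation (IPFM) beat generator
#'
#' Emits a beat each time the running integral of the instantaneous rate
#' crosses a successive integer: `t_k` solves `integral_0^t r(u) du = k`.
#' The integral is accumulated by the trapezoid rule on a fine grid and
#' crossings located by inverse linear interpolation, so a constant rate `r`
#' yields exactly periodic beats at `k / r`.
#'
#' @param rate_fun Function of time (s) returning the instantaneous rate in
#'   beats/s; must be positive and finite on `[0, duration]`.
#' @param duration Length of the recording in seconds.
#' @param dt Integration step (s).
#' @return Numeric vector of beat times in seconds.
#' @export
ipfm_beats <- function(rate_fun, duration, dt = 0.01) {
  tt <- seq(0, duration, by = dt)
  r <- rate_fun(tt)
  if (any(!is.finite(r))) stop("generation error: non-finite instantaneous rate", call. = FALSE)
  if (any(r <= 0)) stop("generation error: non-positive instantaneous rate", call. = FALSE)
  integral <- c(0, cumsum((r[-1L] + r[-length(r)]) / 2) * dt)
  n_beats <- floor(integral[length(integral)])
  if (n_beats < 1L) return(numeric(0))
  stats::approx(integral, tt, xout = seq_len(n_beats), ties = "ordered")$y
}

# internal: piecewise instantaneous-HR profile (bpm) of one subject
hr_profile_fun <- function(hr_rest, hr_peak, hr_plateau, tau, pd) {
  t1 <- pd[["rest"]]
  t2 <- t1 + pd[["exercise"]]
  function(t) {
    ifelse(t < t1, hr_rest,
           ifelse(t < t2, hr_rest + (hr_peak - hr_rest) * (t - t1) / (t2 - t1),
                  hr_plateau + (hr_peak - hr_plateau) * exp(-(t - t2) / tau)))
  }
}

# internal: truncated-normal draw by redraw (keeps seeded determinism)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50L)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Generate one synthetic exercise-test subject
#'
#' Draws a heart-rate profile (rest / linear exercise ramp / mono-exponential
#' recovery) and clinical metadata from the group's distributions, builds the
#' instantaneous RR function as `60000 / HR(t)` plus sinusoidal LF and HF
#' modulation in ms, inverts it to a rate and runs [ipfm_beats()]; white RR
#' noise is then added per interval and beat times rebuilt. Deterministic for
#' a fixed `(config, group, subject_seed)`.
#'
#' @param config A [generator_config()].
#' @param group Group label present in `config`.
#' @param subject_seed Integer seed for this subject.
#' @param id Subject identifier string.
#' @return A `subject_record`: list with `id`, `group`, `meta` (named list of
#'   clinical metadata), `beats` (a [beat_series()]) and `truth` (the drawn
#'   kinetic parameters, for oracle tests).
#' @export
generate_subject <- function(config, group, subject_seed, id = NULL) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$group_params[[group]]
  if (is.null(p)) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  set.seed(as.integer(subject_seed %% 2147483629))

  hr_rest <- rnorm_trunc(1, p$hr_rest_mean, p$hr_rest_sd, 40, 130)
  hr_peak <- rnorm_trunc(1, p$hr_peak_mean, p$hr_peak_sd,
                         max(100, hr_rest + 20), 230)
  hr_plateau <- rnorm_trunc(1, p$hr_plateau_mean, p$hr_plateau_sd,
                            max(50, hr_rest - 25), hr_peak - 5)
  tau <- rnorm_trunc(1, p$tau_mean, p$tau_sd, 20, 200)

  pd <- config$phase_durations
  hrf <- hr_profile_fun(hr_rest, hr_peak, hr_plateau, tau, pd)
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)
  rr_fun <- function(t) {
    60000 / hrf(t) +
      config$lf_amp_ms * sin(2 * pi * config$lf_freq * t + ph1) +
      config$hf_amp_ms * sin(2 * pi * config$hf_freq * t + ph2)
  }
  duration <- sum(pd)
  chk <- 60000 / rr_fun(seq(0, duration, by = 1))
  if (any(!is.finite(chk)) || any(chk <= 20) || any(chk >= 250)) {
    stop(sprintf(
      "generation error: instantaneous HR outside (20, 250) bpm for group '%s' (hr_peak = %.1f, modulation amplitudes %.0f/%.0f ms)",
      group, hr_peak, config$lf_amp_ms, config$hf_amp_ms), call. = FALSE)
  }

  times <- ipfm_beats(function(t) 1000 / rr_fun(t), duration)
  if (config$noise_sd_ms > 0) {
    rr_ms <- diff(times) * 1000 +
      stats::rnorm(length(times) - 1L, 0, config$noise_sd_ms)
    rr_ms <- pmax(rr_ms, 150)
    times <- c(times[1L], times[1L] + cumsum(rr_ms) / 1000)
  }

  t1 <- pd[["rest"]]
  t2 <- t1 + pd[["exercise"]]
  phase <- ifelse(times < t1, "rest", ifelse(times < t2, "exercise", "recovery"))
  beats <- beat_series(times, phase, recovery_onset = t2)
  if (config$ectopy_rate > 0) {
    beats <- inject_ectopy(beats, config$ectopy_rate,
                           seed = (subject_seed + 1L) %% 2147483629)
  }

  sex <- if (stats::runif(1) < p$male_prob) "M" else "F"
  sbp_rest <- rnorm_trunc(1, p$sbp_rest_mean, p$sbp_rest_sd, 85, 200)
  sbp_peak <- sbp_rest + stats::rnorm(1, p$sbp_change_mean, p$sbp_change_sd)
  mwt <- if (group == "control") rnorm_trunc(1, p$mwt_mean, p$mwt_sd, 6, 14)
         else rnorm_trunc(1, p$mwt_mean, p$mwt_sd, 15, 35)
  meta <- list(
    group = group,
    sex = sex,
    age = round(rnorm_trunc(1, p$age_mean, p$age_sd, 18, 85), 1),
    bmi = round(rnorm_trunc(1, p$bmi_mean, p$bmi_sd, 16, 50), 1),
    map_rest = round(rnorm_trunc(1, p$map_rest_mean, p$map_rest_sd, 60, 140), 1),
    sbp_rest = round(sbp_rest, 1),
    sbp_peak = round(sbp_peak, 1),
    nyha = if (group == "control") 1L else sample(1:3, 1, prob = c(0.5, 0.45, 0.05)),
    nsvt = stats::runif(1) < p$nsvt_prob,
    syncope = stats::runif(1) < p$syncope_prob,
    fh_scd = stats::runif(1) < p$fh_scd_prob,
    mwt = round(mwt, 1),
    la_diameter = round(rnorm_trunc(1, p$la_mean, p$la_sd, 25, 60), 1),
    ef = round(rnorm_trunc(1, p$ef_mean, p$ef_sd, 40, 80), 1),
    lvot_gradient_peak = round(stats::rlnorm(1, p$lvot_meanlog, p$lvot_sdlog), 1),
    e_eprime_lateral = round(rnorm_trunc(1, p$ee_mean, p$ee_sd, 3, 20), 2),
    peak_vo2 = round(rnorm_trunc(1, p$vo2_mean, p$vo2_sd, 10, 60), 1),
    peak_workload = round(rnorm_trunc(1, p$workload_mean, p$workload_sd, 40, 450)),
    rer = round(stats::runif(1, 1.06, 1.25), 2)
  )
  meta$abpr <- unname(classify_abpr(meta$sbp_rest, meta$sbp_peak) == "abnormal")
  meta$risk_factor_count <- sum(meta$nsvt, meta$syncope, meta$mwt >= 30,
                                meta$fh_scd, meta$abpr)

  structure(list(id = if (is.null(id)) sprintf("%s_%05d", group, subject_seed %% 100000L) else id,
                 group = group, meta = meta, beats = beats,
                 truth = list(hr_rest = hr_rest, hr_peak = hr_peak,
                              hr_plateau = hr_plateau, tau = tau,
                              subject_seed = as.integer(subject_seed %% 2147483629))),
            class = "subject_record")
}

#' Generate a synthetic cohort
#'
#' One [generate_subject()] per subject, with per-subject seeds derived
#' deterministically from the master seed.
#'
#' @param config A [generator_config()].
#' @return An `hrr_cohort`: list of `subject_record`s with the config attached
#'   as attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  subjects <- list()
  idx <- 0L
  for (g in names(config$n_per_group)) {
    for (k in seq_len(config$n_per_group[[g]])) {
      idx <- idx + 1L
      sseed <- (as.double(config$seed) * 10007 + idx * 7919) %% 2147483629
      subj <- tryCatch(
        generate_subject(config, g, sseed, id = sprintf("S%03d_%s", idx, g)),
        error = function(e) stop(sprintf("subject %d (group %s): %s",
                                         idx, g, conditionMessage(e)),
                                 call. = FALSE))
      subjects[[length(subjects) + 1L]] <- subj
    }
  }
  structure(subjects, class = "hrr_cohort", config = config)
}

#' @export
print.hrr_cohort <- function(x, ...) {
  groups <- vapply(x, function(s) s$group, character(1))
  cat(sprintf("<hrr_cohort> %d subjects: %s\n", length(x),
              paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Inject ectopic beats into a beat series
#'
#' Emulates premature beats as produced by an irritable focus: a randomly
#' selected beat is displaced early to a coupling interval of 40-60% of the
#' local RR; the following beat is left in place, which creates the
#' compensatory pause. Used to exercise the downstream artifact filter.
#'
#' @param beats A [beat_series()].
#' @param rate Ectopic events per minute (Poisson mean over the recording).
#' @param seed Integer seed.
#' @return A [beat_series()] with attribute `n_ectopic` recording the number
#'   of injected events.
#' @export
inject_ectopy <- function(beats, rate, seed = 1L) {
  stopifnot(inherits(beats, "beat_series"))
  if (rate < 0) stop("ectopy rate must be >= 0", call. = FALSE)
  out <- beats
  if (rate == 0) {
    attr(out, "n_ectopic") <- 0L
    return(out)
  }
  set.seed(as.integer(seed %% 2147483629))
  span_min <- diff(range(beats$times)) / 60
  n_events <- stats::rpois(1, rate * span_min)
  n <- length(beats$times)
  eligible <- 3:(n - 2L)
  n_events <- min(n_events, length(eligible))
  if (n_events > 0) {
    picks <- sort(sample(eligible, n_events))
    # drop picks whose neighbourhood overlaps a previous pick
    keep <- c(TRUE, diff(picks) > 2)
    picks <- picks[keep]
    times <- out$times
    for (i in picks) {
      local_rr <- times[i] - times[i - 1L]
      times[i] <- times[i - 1L] + stats::runif(1, 0.4, 0.6) * local_rr
    }
    out$times <- times
    attr(out, "n_ectopic") <- length(picks)
  } else {
    attr(out, "n_ectopic") <- 0L
  }
  out
}
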