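#' Absolute heart rate recovery
#'
#' The fall in heart rate from peak exercise to a recovery time point,
#' `hr_peak - hr_t`, in beats/min. A negative value (HR above peak during
#' recovery) is retained for QC, with a warning.
#'
#' @param hr_peak Peak exercise HR (beats/min).
#' @param hr_t HR at the recovery time point (beats/min).
#' @return Beats/min.
#' @export
#' @examples
#' absolute_hrr(176.8, 123.2) # 53.6
absolute_hrr <- function(hr_peak, hr_t) {
  if (any(!is.finite(hr_peak)) || any(!is.finite(hr_t)) ||
      any(hr_peak <= 0) || any(hr_t <= 0)) {
    stop("heart rates must be finite and positive", call. = FALSE)
  }
  out <- hr_peak - hr_t
  if (any(out < 0)) {
    warning("negative heart-rate recovery (HR above peak); retained for QC",
            call. = FALSE)
  }
  out
}

#' Heart rate recovery as a percentage of peak HR
#'
#' @param hrr_abs Absolute HRR (beats/min).
#' @param hr_peak Peak HR (beats/min), > 0.
#' @return Percent.
#' @export
pct_of_peak <- function(hrr_abs, hr_peak) {
  if (any(!is.finite(hr_peak)) || any(hr_peak <= 0)) {
    stop("hr_peak must be finite and > 0", call. = FALSE)
  }
  100 * hrr_abs / hr_peak
}

#' Heart rate recovery as a percentage of heart-rate reserve
#'
#' Normalises the recovery drop to the rise from baseline to peak exercise
#' (`hr_peak - hr_rest`, the heart-rate reserve). 100% means full return to
#' the resting rate.
#'
#' @param hrr_abs Absolute HRR (beats/min).
#' @param hr_peak Peak HR (beats/min).
#' @param hr_rest Resting HR (beats/min); must be < `hr_peak`.
#' @return Percent.
#' @export
pct_of_reserve <- function(hrr_abs, hr_peak, hr_rest) {
  if (any(!is.finite(hr_peak)) || any(!is.finite(hr_rest))) {
    stop("heart rates must be finite", call. = FALSE)
  }
  if (any(hr_peak <= hr_rest)) {
    stop("undefined reserve: hr_peak must exceed hr_rest", call. = FALSE)
  }
  100 * hrr_abs / (hr_peak - hr_rest)
}

#' Classify the blood pressure response to exercise
#'
#' An abnormal blood pressure response (ABPR) is a rise in systolic blood
#' pressure from rest to peak exercise of less than 20 mm Hg. A rise of
#' exactly 20 mm Hg is classified normal (the rule is a strict "< 20").
#'
#' @param sbp_rest,sbp_peak Systolic pressures (mm Hg), positive.
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_abpr <- function(sbp_rest, sbp_peak) {
  if (any(!is.finite(sbp_rest)) || any(!is.finite(sbp_peak)) ||
      any(sbp_rest <= 0) || any(sbp_peak <= 0)) {
    stop("blood pressures must be finite and positive", call. = FALSE)
  }
  ifelse(sbp_peak - sbp_rest < 20, "abnormal", "normal")
}

#' Per-subject heart rate recovery profile
#'
#' Computes the full set of recovery statistics from a subject's beat series:
#' resting and peak HR, heart-rate reserve, the 10-beat mean HR at 1, 2 and 3
#' minutes of recovery, and the nine recovery statistics (absolute reduction,
#' reduction as % of peak HR, reduction as % of heart-rate reserve, at each
#' time point). A time point whose HR cannot be estimated (insufficient
#' accepted beats) is reported as `NA` and listed in the `missing` attribute;
#' other time points remain populated.
#'
#' @param subject A `subject_record` (see [generate_subject()]) or a
#'   [beat_series()].
#' @return A list of class `hrr_metrics` with elements `hr_rest`, `hr_peak`,
#'   `delta_hr`, `hr_at` (named by seconds), `hrr_abs`, `hrr_pct_peak`,
#'   `hrr_pct_reserve`.
#' @export
compute_hrr_profile <- function(subject) {
  beats <- if (inherits(subject, "subject_record")) subject$beats else subject
  stopifnot(inherits(beats, "beat_series"))
  hr_rest <- resting_hr(beats)
  hr_pk <- peak_hr(beats)
  t0 <- beats$recovery_onset
  if (is.na(t0)) stop("insufficient data: no recovery phase", call. = FALSE)
  tps <- c(`60` = 60, `120` = 120, `180` = 180)
  hr_at <- vapply(tps, function(dt) {
    tryCatch(as.numeric(ten_beat_hr(beats, t0 + dt)),
             error = function(e) NA_real_)
  }, numeric(1))
  hrr_abs <- ifelse(is.na(hr_at), NA_real_, hr_pk - hr_at)
  if (any(hrr_abs < 0, na.rm = TRUE)) {
    warning("negative heart-rate recovery at some time point; retained for QC",
            call. = FALSE)
  }
  res <- structure(list(
    hr_rest = hr_rest,
    hr_peak = hr_pk,
    delta_hr = hr_pk - hr_rest,
    hr_at = hr_at,
    hrr_abs = hrr_abs,
    hrr_pct_peak = 100 * hrr_abs / hr_pk,
    hrr_pct_reserve = if (hr_pk - hr_rest > 1e-6) 100 * hrr_abs / (hr_pk - hr_rest)
                      else stop("undefined reserve: hr_peak must exceed hr_rest",
                                call. = FALSE)
  ), class = "hrr_metrics")
  attr(res, "missing") <- names(tps)[is.na(hr_at)]
  res
}

#' @export
print.hrr_metrics <- function(x, ...) {
  cat(sprintf("<hrr_metrics> rest %.1f, peak %.1f, reserve %.1f beats/min\n",
              x$hr_rest, x$hr_peak, x$delta_hr))
  for (tp in names(x$hr_at)) {
    cat(sprintf("  t=%ss: HR %.1f | drop %.1f bpm | %.1f%% of peak | %.1f%% of reserve\n",
                tp, x$hr_at[[tp]], x$hrr_abs[[tp]],
                x$hrr_pct_peak[[tp]], x$hrr_pct_reserve[[tp]]))
  }
  invisible(x)
}
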