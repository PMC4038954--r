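#' Beat-time series with exercise-phase annotations
#'
#' The primitive input of every analysis in hrrkit: one timestamp per
#' heartbeat, each labelled with the test phase it belongs to
#' (`rest`, `exercise` or `recovery`), plus the recovery onset time
#' (the moment the workload returns to zero; all recovery times are
#' referenced to this origin).
#'
#' @param times Numeric vector of beat times in seconds from recording start,
#'   strictly increasing.
#' @param phase Character vector (same length) of phase labels, each one of
#'   `"rest"`, `"exercise"`, `"recovery"`; phases must be contiguous and in
#'   that order (phases may be absent, but never interleaved).
#' @param recovery_onset Time (s) at which recovery starts. Defaults to the
#'   midpoint between the last exercise beat and the first recovery beat
#'   (or the first recovery beat if there is no exercise phase).
#' @return An object of class `beat_series`: a list with elements `times`,
#'   `phase` and `recovery_onset`.
#' @export
#' @examples
#' bs <- beat_series(seq(0, 10, by = 0.8), rep("rest", 13))
beat_series <- function(times, phase, recovery_onset = NULL) {
  times <- as.numeric(times)
  phase <- as.character(phase)
  if (length(times) != length(phase)) {
    stop("`times` and `phase` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a beat series needs at least 2 beats", call. = FALSE)
  }
  if (any(!is.finite(times))) stop("non-finite beat times", call. = FALSE)
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("beat times must be strictly increasing (violated at beat %d)", bad),
         call. = FALSE)
  }
  valid <- c("rest", "exercise", "recovery")
  if (any(!phase %in% valid)) {
    stop(sprintf("unknown phase label '%s'", setdiff(phase, valid)[1L]), call. = FALSE)
  }
  runs <- rle(phase)$values
  if (anyDuplicated(runs) || is.unsorted(match(runs, valid))) {
    stop("phases must be contiguous and ordered rest -> exercise -> recovery",
         call. = FALSE)
  }
  if (is.null(recovery_onset)) {
    i_rec <- which(phase == "recovery")
    if (length(i_rec)) {
      i0 <- i_rec[1L]
      recovery_onset <- if (i0 > 1L && phase[i0 - 1L] == "exercise") {
        (times[i0 - 1L] + times[i0]) / 2
      } else {
        times[i0]
      }
    } else {
      recovery_onset <- NA_real_
    }
  }
  structure(list(times = times, phase = phase,
                 recovery_onset = as.numeric(recovery_onset)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s\n",
              length(x$times), diff(range(x$times))))
  tab <- table(factor(x$phase, levels = c("rest", "exercise", "recovery")))
  cat(sprintf("  phases: rest %d | exercise %d | recovery %d (onset %.1f s)\n",
              tab[["rest"]], tab[["exercise"]], tab[["recovery"]],
              x$recovery_onset))
  invisible(x)
}

#' RR-interval tachogram
#'
#' A sequence of RR intervals (ms) with sample timestamps (s). Non-uniform
#' tachograms carry one sample per beat, stamped at the time of the beat that
#' closes the interval; uniform tachograms are evenly resampled at
#' `sampling_rate` Hz for the Welch and autoregressive spectral estimators.
#'
#' @param time Numeric sample times in seconds.
#' @param rr Numeric RR values in milliseconds.
#' @param uniform Logical; is the series evenly spaced?
#' @param sampling_rate Sampling rate in Hz (required when `uniform`).
#' @return An object of class `tachogram`.
#' @export
tachogram <- function(time, rr, uniform = FALSE, sampling_rate = NULL) {
  time <- as.numeric(time)
  rr <- as.numeric(rr)
  if (length(time) != length(rr)) stop("`time` and `rr` lengths differ", call. = FALSE)
  if (any(diff(time) <= 0)) stop("tachogram times must be strictly increasing", call. = FALSE)
  if (isTRUE(uniform)) {
    if (is.null(sampling_rate) || sampling_rate <= 0) {
      stop("uniform tachogram requires a positive `sampling_rate`", call. = FALSE)
    }
    if (length(time) > 2L &&
        max(abs(diff(time) - 1 / sampling_rate)) > 1e-6 / sampling_rate) {
      stop("uniform tachogram has non-constant spacing", call. = FALSE)
    }
  }
  structure(list(time = time, rr = rr, uniform = isTRUE(uniform),
                 sampling_rate = if (isTRUE(uniform)) sampling_rate else NA_real_),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples, %.1f s span, %s\n",
              length(x$rr), diff(range(x$time)),
              if (x$uniform) sprintf("uniform @ %g Hz", x$sampling_rate)
              else "non-uniform"))
  invisible(x)
}

# internal: subset a beat_series to one phase (times unchanged)
phase_beats <- function(beats, phase) {
  stopifnot(inherits(beats, "beat_series"))
  idx <- beats$phase == phase
  list(times = beats$times[idx], n = sum(idx))
}
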