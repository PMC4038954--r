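#' Extract the RR tachogram of one test phase
#'
#' Converts beat times to RR intervals, `RR_i = (t_i - t_{i-1}) * 1000` ms,
#' each stamped at the time of the interval-closing beat.
#'
#' @param beats A [beat_series()].
#' @param phase Phase label to extract (`"rest"`, `"exercise"`, `"recovery"`).
#' @return A non-uniform [tachogram()].
#' @export
rr_from_beats <- function(beats, phase = c("recovery", "rest", "exercise")) {
  phase <- match.arg(phase)
  pb <- phase_beats(beats, phase)
  if (pb$n < 2L) {
    stop(sprintf("insufficient data: need >= 2 beats in phase '%s', have %d",
                 phase, pb$n), call. = FALSE)
  }
  tachogram(time = pb$times[-1L], rr = diff(pb$times) * 1000)
}

#' Reject artifactual RR intervals
#'
#' Applies two rules borrowed from common HRV practice (the recording
#' technique names the artifact problem but no rule): an RR interval is
#' rejected if it falls outside the physiological window \[300, 2000\] ms, or
#' if it differs from the previous *accepted* RR by more than 20%. Rejected
#' samples are replaced by linear interpolation between accepted neighbours so
#' the series stays gap-free for spectral analysis; the `accepted` attribute
#' marks which samples are real, and windowed heart-rate means use only those.
#'
#' @param tg A non-uniform [tachogram()].
#' @param rr_min,rr_max Absolute bounds in ms.
#' @param max_delta Maximal relative jump from the previous accepted RR.
#' @return The cleaned [tachogram()] with attributes:
#'   `accepted` (logical mask), `rejections` (data frame of index, time,
#'   rr, reason), and `high_rejection` (TRUE if > 20% of samples rejected —
#'   analysis proceeds but downstream results should be flagged).
#' @export
filter_artifacts <- function(tg, rr_min = 300, rr_max = 2000, max_delta = 0.20) {
  stopifnot(inherits(tg, "tachogram"))
  if (tg$uniform) stop("filter_artifacts expects a non-uniform tachogram", call. = FALSE)
  n <- length(tg$rr)
  accepted <- rep(TRUE, n)
  reason <- character(n)
  last_ok <- NA_real_
  for (i in seq_len(n)) {
    rr <- tg$rr[i]
    if (rr < rr_min) {
      accepted[i] <- FALSE; reason[i] <- "below-floor"
    } else if (rr > rr_max) {
      accepted[i] <- FALSE; reason[i] <- "above-ceiling"
    } else if (!is.na(last_ok) && abs(rr - last_ok) / last_ok > max_delta) {
      accepted[i] <- FALSE; reason[i] <- "delta-jump"
    }
    if (accepted[i]) last_ok <- rr
  }
  if (!any(accepted)) stop("no RR intervals survive artifact filtering", call. = FALSE)
  rr_clean <- tg$rr
  if (any(!accepted)) {
    rr_clean[!accepted] <- stats::approx(tg$time[accepted], tg$rr[accepted],
                                         xout = tg$time[!accepted],
                                         rule = 2)$y
  }
  out <- tachogram(tg$time, rr_clean)
  rej <- data.frame(index = which(!accepted),
                    time = tg$time[!accepted],
                    rr = tg$rr[!accepted],
                    reason = reason[!accepted],
                    stringsAsFactors = FALSE)
  attr(out, "accepted") <- accepted
  attr(out, "rejections") <- rej
  attr(out, "high_rejection") <- mean(!accepted) > 0.20
  if (attr(out, "high_rejection")) {
    warning(sprintf("%.0f%% of RR intervals rejected; results flagged",
                    100 * mean(!accepted)), call. = FALSE)
  }
  out
}

# internal: accepted RR intervals over the whole recording
accepted_rr <- function(beats) {
  if (length(beats$times) < 2L) stop("insufficient data: < 2 beats", call. = FALSE)
  tg <- tachogram(beats$times[-1L], diff(beats$times) * 1000)
  cl <- suppressWarnings(filter_artifacts(tg))
  acc <- attr(cl, "accepted")
  list(time = tg$time[acc], rr = tg$rr[acc])
}

#' Mean heart rate from 10 consecutive beats around a time point
#'
#' The recovery heart rate at each minute is taken as the mean HR over 10
#' consecutive accepted RR intervals whose window is centred on `t`: the 5
#' intervals ending before `t` and the 5 starting at or after it, shifted
#' inward at recording edges. Artifact-rejected intervals are skipped, not
#' interpolated, so the estimate is never biased by synthetic samples.
#'
#' @param beats A [beat_series()].
#' @param t Target time in seconds (absolute recording time).
#' @return Mean HR in beats/min, with attribute `span` giving the actual
#'   start/end times of the window used.
#' @export
ten_beat_hr <- function(beats, t) {
  ac <- accepted_rr(beats)
  n <- length(ac$rr)
  near <- abs(ac$time - t) <= 30
  if (sum(near) < 10L) {
    stop(sprintf(
      "insufficient data: %d accepted beats within 30 s of t = %.1f s (need 10)",
      sum(near), t), call. = FALSE)
  }
  k <- sum(ac$time < t)            # intervals ending before t
  lo <- k - 4L
  hi <- k + 5L
  if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
  if (hi > n) { lo <- lo - (hi - n); hi <- n }
  lo <- max(lo, 1L)
  idx <- lo:hi
  hr <- mean(60000 / ac$rr[idx])
  attr(hr, "span") <- c(start = ac$time[lo] - ac$rr[lo] / 1000, end = ac$time[hi])
  hr
}

#' Resting heart rate
#'
#' 10-beat mean HR at the midpoint of the rest phase.
#'
#' @param beats A [beat_series()].
#' @return Beats/min.
#' @export
resting_hr <- function(beats) {
  pb <- phase_beats(beats, "rest")
  if (pb$n < 11L) stop("insufficient data: rest phase needs >= 11 beats", call. = FALSE)
  mid <- (pb$times[1L] + pb$times[pb$n]) / 2
  as.numeric(ten_beat_hr(beats, mid))
}

#' Peak exercise heart rate
#'
#' Maximum 10-interval rolling mean HR over accepted intervals of the
#' exercise phase.
#'
#' @param beats A [beat_series()].
#' @return Beats/min.
#' @export
peak_hr <- function(beats) {
  pb <- phase_beats(beats, "exercise")
  if (pb$n < 11L) stop("insufficient data: exercise phase needs >= 11 beats", call. = FALSE)
  ac <- accepted_rr(beats)
  inph <- ac$time >= pb$times[2L] & ac$time <= pb$times[pb$n]
  rr <- ac$rr[inph]
  if (length(rr) < 10L) stop("insufficient data: < 10 accepted exercise intervals", call. = FALSE)
  hr <- 60000 / rr
  roll <- stats::filter(hr, rep(1 / 10, 10), sides = 1)
  max(roll, na.rm = TRUE)
}

#' Resample a tachogram onto a uniform grid
#'
#' Cubic-spline interpolation onto an evenly spaced grid (default 4 Hz, the
#' common HRV convention) spanning the input. The mean is *not* removed here;
#' detrending belongs to the spectral estimators.
#'
#' @param tg A cleaned non-uniform [tachogram()] spanning at least 60 s.
#' @param rate Target sampling rate in Hz.
#' @return A uniform [tachogram()] of length `floor(span * rate) + 1`.
#' @export
resample_uniform <- function(tg, rate = 4) {
  stopifnot(inherits(tg, "tachogram"))
  if (tg$uniform) return(tg)
  span <- tg$time[length(tg$time)] - tg$time[1L]
  if (span < 60) {
    stop(sprintf("insufficient data: tachogram spans %.1f s (< 60 s)", span),
         call. = FALSE)
  }
  grid <- tg$time[1L] + seq_len(floor(span * rate) + 1L) / rate - 1 / rate
  vals <- stats::spline(tg$time, tg$rr, xout = grid, method = "natural")$y
  tachogram(grid, vals, uniform = TRUE, sampling_rate = rate)
}
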