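# Tri-method RR spectral analysis. All estimators return a spectral_result
# on a grid covering the VLF/LF/HF range; band_powers() reduces any of them
# to the Task-Force band integrals, normalised units and the LF:HF ratio.

new_spectral_result <- function(frequencies, psd, method, parameters = list()) {
  if (any(psd < -1e-9)) stop("negative PSD values", call. = FALSE)
  psd <- pmax(psd, 0)
  if (any(diff(frequencies) <= 0)) stop("frequency grid must be increasing", call. = FALSE)
  structure(list(frequencies = frequencies, psd = psd, method = method,
                 parameters = parameters),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> method=%s, %d bins over [%.4f, %.3f] Hz\n",
              x$method, length(x$frequencies), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

# trapezoid integral of y over x
trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

# trapezoid integral restricted to [lo, hi], with interpolated band edges
band_integral <- function(f, p, lo, hi) {
  lo <- max(lo, min(f)); hi <- min(hi, max(f))
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  fi <- c(lo, f[inside], hi)
  pi <- c(stats::approx(f, p, xout = lo)$y, p[inside],
          stats::approx(f, p, xout = hi)$y)
  trapz(fi, pi)
}

# remove mean and linear trend
detrend_linear <- function(time, x) {
  stats::lm.fit(cbind(1, time - mean(time)), x)$residuals
}

#' Welch power spectral density of a uniform tachogram
#'
#' Mean and linear trend are removed (the recovery tachogram is
#' nonstationary), the series is split into Hann-windowed segments with 50%
#' overlap, and segment periodograms are averaged. Density scaling uses the
#' window power `sum(w^2)`, so the one-sided PSD integrates to the detrended
#' series variance (Parseval).
#'
#' @param tg A uniform [tachogram()] at least as long as one segment.
#' @param segment_s Segment length in seconds (default 60 s, suited to a
#'   180-s recovery record).
#' @param overlap Fractional overlap between segments.
#' @return A `spectral_result` (ms^2/Hz on a grid from 0 to Nyquist).
#' @export
welch_psd <- function(tg, segment_s = 60, overlap = 0.5) {
  stopifnot(inherits(tg, "tachogram"))
  if (!tg$uniform) stop("welch_psd needs a uniform tachogram; resample first", call. = FALSE)
  fs <- tg$sampling_rate
  x <- detrend_linear(tg$time, tg$rr)
  nseg <- round(segment_s * fs)
  if (length(x) < nseg) {
    stop(sprintf("insufficient data: %d samples, need >= %d (one %g-s segment)",
                 length(x), nseg, segment_s), call. = FALSE)
  }
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / nseg))  # periodic Hann
  U <- sum(w^2)
  nh <- floor(nseg / 2)
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    X <- stats::fft(seg)
    P <- Mod(X[1:(nh + 1L)])^2 / (fs * U)
    P[2:nh] <- 2 * P[2:nh]  # one-sided (DC and Nyquist not doubled)
    acc <- acc + P
  }
  new_spectral_result(frequencies = (0:nh) * fs / nseg,
                      psd = acc / length(starts),
                      method = "welch",
                      parameters = list(segment_s = segment_s,
                                        overlap = overlap, fs = fs,
                                        n_segments = length(starts)))
}

#' Levinson-Durbin recursion
#'
#' Solves the Yule-Walker equations for an AR(p) model from an
#' autocovariance sequence, returning the autoregressive coefficients (in the
#' convention `x_t = sum_k a_k x_{t-k} + e_t`), the reflection coefficients,
#' and the innovation variance at the final order (non-increasing in order).
#'
#' @param acov Autocovariance sequence `gamma(0), gamma(1), ...`;
#'   `gamma(0) > 0`.
#' @param order Model order `p < length(acov)`.
#' @return List with `a` (length `p`), `reflection` (length `p`),
#'   `sigma2` (innovation variance) and `sigma2_trace` (variance after each
#'   order).
#' @export
levinson_durbin <- function(acov, order) {
  acov <- as.numeric(acov)
  if (length(acov) < order + 1L) stop("need order + 1 autocovariance values", call. = FALSE)
  if (!is.finite(acov[1L]) || acov[1L] <= 0) {
    stop("numerical error: gamma(0) must be positive", call. = FALSE)
  }
  a <- numeric(0)
  E <- acov[1L]
  refl <- numeric(order)
  trace <- numeric(order)
  for (m in seq_len(order)) {
    num <- acov[m + 1L]
    if (m > 1L) num <- num - sum(a * acov[m:2])
    k <- num / E
    if (!is.finite(k) || abs(k) >= 1 + 1e-10) {
      stop(sprintf(
        "numerical error: autocovariance not positive definite at order %d (reflection %.4f)",
        m, k), call. = FALSE)
    }
    a <- if (m == 1L) k else c(a - k * rev(a), k)
    E <- E * (1 - k^2)
    refl[m] <- k
    trace[m] <- E
    if (E <= 0) {
      stop(sprintf("numerical error: innovation variance <= 0 at order %d", m),
           call. = FALSE)
    }
  }
  list(a = a, reflection = refl, sigma2 = E, sigma2_trace = trace)
}

#' Autoregressive power spectral density (Yule-Walker / Levinson-Durbin)
#'
#' Fits an AR(`order`) model to the detrended series via [levinson_durbin()]
#' on the biased autocovariance estimate and evaluates
#' `sigma^2 / |1 - sum_k a_k e^(-2 pi i f k / fs)|^2`, scaled one-sided so the
#' integral approximates the series variance.
#'
#' @param tg A uniform [tachogram()].
#' @param order AR model order (default 16, a common HRV choice).
#' @param n_freq Number of grid points from 0 to Nyquist.
#' @return A `spectral_result`.
#' @export
ar_psd <- function(tg, order = 16, n_freq = 1025) {
  stopifnot(inherits(tg, "tachogram"))
  if (!tg$uniform) stop("ar_psd needs a uniform tachogram; resample first", call. = FALSE)
  fs <- tg$sampling_rate
  x <- detrend_linear(tg$time, tg$rr)
  if (length(x) <= order + 1L) stop("insufficient data for requested AR order", call. = FALSE)
  acov <- as.numeric(stats::acf(x, lag.max = order, type = "covariance",
                                demean = FALSE, plot = FALSE)$acf)
  freq <- seq(0, fs / 2, length.out = n_freq)
  if (order == 0L) {
    psd <- rep(2 * acov[1L] / fs, n_freq)
    psd[c(1L, n_freq)] <- psd[c(1L, n_freq)] / 2
    ld <- list(a = numeric(0), reflection = numeric(0), sigma2 = acov[1L])
  } else {
    ld <- levinson_durbin(acov, order)
    ks <- seq_len(order)
    A <- 1 - exp(-2i * pi * outer(freq, ks) / fs) %*% ld$a
    psd <- 2 * ld$sigma2 / (fs * Mod(A)^2)
    psd[c(1L, n_freq)] <- psd[c(1L, n_freq)] / 2
  }
  new_spectral_result(frequencies = freq, psd = as.numeric(psd),
                      method = "ar",
                      parameters = list(order = order, fs = fs,
                                        sigma2 = ld$sigma2, a = ld$a))
}

#' Lomb-Scargle power spectral density of an uneven tachogram
#'
#' Classical Lomb-Scargle periodogram evaluated directly on the unevenly
#' sampled RR series (its purpose: no resampling). The series is linearly
#' detrended, and the raw periodogram is converted to a one-sided density
#' (ms^2/Hz) by the factor `2 * span / n`, which makes the main-lobe
#' integral of a pure sinusoid of amplitude A recover band power A^2/2
#' (uneven sampling additionally scatters a small leakage floor across the
#' grid).
#'
#' @param tg A non-uniform [tachogram()] with >= 60 samples spanning
#'   >= 120 s.
#' @param oversample Frequency oversampling factor relative to `1/span`.
#' @param f_max Upper frequency bound of the grid (Hz).
#' @return A `spectral_result` on a grid from 0.0033 Hz to `f_max`.
#' @export
lomb_scargle_psd <- function(tg, oversample = 4, f_max = 0.5) {
  stopifnot(inherits(tg, "tachogram"))
  tt <- tg$time
  if (length(tt) < 60L) stop("insufficient data: need >= 60 samples", call. = FALSE)
  span <- max(tt) - min(tt)
  if (span < 1e-9) stop("degenerate time spacing", call. = FALSE)
  if (span < 120) stop("insufficient data: span must be >= 120 s", call. = FALSE)
  x <- detrend_linear(tt, tg$rr)
  freqs <- seq(0.0033, f_max, by = 1 / (oversample * span))
  P <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * tt)), sum(cos(2 * w * tt))) / (2 * w)
    ct <- cos(w * (tt - tau))
    st <- sin(w * (tt - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  v <- sum(x^2) / length(x)
  psd <- if (v > 1e-12) P * 2 * span / length(tt) else P * 0
  new_spectral_result(frequencies = freqs, psd = psd, method = "lomb_scargle",
                      parameters = list(oversample = oversample, span = span,
                                        variance = v))
}

#' VLF / LF / HF band powers, normalised units and LF:HF ratio
#'
#' Trapezoidal integration of a PSD over the Task-Force bands:
#' VLF 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. LF and HF are
#' normalised by total power minus the very-low-frequency component,
#' so `lf_nu + hf_nu = 1` by construction; values are fractions in \[0, 1\].
#'
#' @param spec A `spectral_result` whose grid covers \[0.0033, 0.4\] Hz.
#' @param bands Named list of band edges (Hz).
#' @return A list of class `band_powers`: `vlf`, `lf`, `hf`, `total` (ms^2),
#'   `lf_nu`, `hf_nu`, `lf_hf_ratio` (NA when HF power is zero), `method`.
#' @export
band_powers <- function(spec,
                        bands = list(vlf = c(0.0033, 0.04),
                                     lf = c(0.04, 0.15),
                                     hf = c(0.15, 0.4))) {
  stopifnot(inherits(spec, "spectral_result"))
  f <- spec$frequencies
  if (min(f) > 0.0034 || max(f) < 0.4 - 1e-9) {
    stop("frequency grid must cover [0.0033, 0.4] Hz", call. = FALSE)
  }
  p <- spec$psd
  vlf <- band_integral(f, p, bands$vlf[1], bands$vlf[2])
  lf <- band_integral(f, p, bands$lf[1], bands$lf[2])
  hf <- band_integral(f, p, bands$hf[1], bands$hf[2])
  denom <- lf + hf
  structure(list(vlf = vlf, lf = lf, hf = hf, total = vlf + lf + hf,
                 lf_nu = if (denom > 0) lf / denom else NA_real_,
                 hf_nu = if (denom > 0) hf / denom else NA_real_,
                 lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
                 method = spec$method),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf(
    "<band_powers> [%s] VLF %.1f | LF %.1f | HF %.1f ms^2 | LF %.2f n.u. | LF:HF %.2f\n",
    x$method, x$vlf, x$lf, x$hf, x$lf_nu, x$lf_hf_ratio))
  invisible(x)
}

#' Band powers of the 3-minute recovery tachogram
#'
#' Extracts the first 180 s of the recovery phase, filters artifacts, and
#' routes the series to the chosen spectral estimator: Welch and AR receive
#' the artifact-interpolated series resampled to a uniform grid; Lomb-Scargle
#' receives the raw accepted samples unevenly spaced.
#'
#' @param subject A `subject_record` or [beat_series()].
#' @param method `"welch"`, `"ar"` or `"lomb_scargle"`.
#' @param resample_rate Uniform resampling rate (Hz) for Welch/AR.
#' @param ar_order AR model order.
#' @return A `band_powers` object (attribute `spectrum` holds the full
#'   `spectral_result`, attribute `flagged` the high-rejection flag).
#' @export
recovery_spectrum <- function(subject,
                              method = c("welch", "ar", "lomb_scargle"),
                              resample_rate = 4, ar_order = 16) {
  method <- match.arg(method)
  beats <- if (inherits(subject, "subject_record")) subject$beats else subject
  stopifnot(inherits(beats, "beat_series"))
  t0 <- beats$recovery_onset
  tg <- rr_from_beats(beats, "recovery")
  keep <- tg$time <= t0 + 180
  if (sum(keep) < 3L || max(tg$time[keep]) - t0 < 170) {
    stop("insufficient data: recovery phase must cover ~180 s", call. = FALSE)
  }
  tg <- tachogram(tg$time[keep], tg$rr[keep])
  clean <- suppressWarnings(filter_artifacts(tg))
  if (method == "lomb_scargle") {
    acc <- attr(clean, "accepted")
    raw <- tachogram(tg$time[acc], tg$rr[acc])
    spec <- lomb_scargle_psd(raw)
  } else {
    uni <- resample_uniform(clean, rate = resample_rate)
    spec <- if (method == "welch") welch_psd(uni) else ar_psd(uni, order = ar_order)
  }
  bp <- band_powers(spec)
  attr(bp, "spectrum") <- spec
  attr(bp, "flagged") <- isTRUE(attr(clean, "high_rejection"))
  bp
}
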