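test_that("levinson_durbin solves Yule-Walker in closed form", {
  ld <- levinson_durbin(c(1, 0.6, 0.36), 2)
  expect_equal(ld$a, c(0.6, 0), tolerance = 1e-12)
  expect_equal(ld$sigma2, 0.64, tolerance = 1e-12)

  ldw <- levinson_durbin(c(1, 0, 0, 0), 3)
  expect_equal(ldw$a, c(0, 0, 0))
  expect_equal(ldw$sigma2, 1)

  expect_error(levinson_durbin(c(0, 0.5), 1), "positive")
  expect_error(levinson_durbin(c(1, 1.2), 1), "positive definite")
})

test_that("levinson_durbin agrees with a direct Yule-Walker solve and is consistent", {
  set.seed(8)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 4000))
  g <- as.numeric(stats::acf(x, lag.max = 6, type = "covariance",
                             demean = TRUE, plot = FALSE)$acf)
  ld <- levinson_durbin(g, 6)
  oracle <- solve(stats::toeplitz(g[1:6]), g[2:7])  # independent linear solve
  expect_equal(ld$a, as.numeric(oracle), tolerance = 1e-9)
  expect_lt(abs(ld$a[1] - 0.8), 0.05 + abs(sum(ld$a[-1])))
  ld1 <- levinson_durbin(g, 1)
  expect_lt(abs(ld1$a - 0.8), 0.05)
  # innovation variance non-increasing in order
  expect_true(all(diff(ld$sigma2_trace) <= 1e-12))
})

test_that("welch_psd: null power for constant input, A^2/2 for a pure tone", {
  const <- tone_tachogram(0.25, 0)
  bp0 <- band_powers(welch_psd(const))
  expect_lt(bp0$total, 1e-6)

  tone <- tone_tachogram(0.25, 30, 0.7)
  bp <- band_powers(welch_psd(tone))
  expect_equal(bp$hf, 450, tolerance = 0.05)
  expect_lt(bp$lf, 0.02 * bp$hf)

  expect_error(welch_psd(tone_tachogram(0.25, 30, span = 50)),
               "insufficient data")
})

test_that("welch_psd satisfies Parseval on white noise (seed-averaged)", {
  set.seed(12)
  ratios <- replicate(12, {
    tg <- tone_tachogram(0.25, 0, noise_sd = 20)
    w <- welch_psd(tg)
    x <- hrrkit:::detrend_linear(tg$time, tg$rr)
    hrrkit:::trapz(w$frequencies, w$psd) / (sum(x^2) / length(x))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("ar_psd: flat for white noise, sharp for a tone, degenerate order 0", {
  set.seed(3)
  noise <- tone_tachogram(0.25, 0, span = 1000, noise_sd = 25)
  sp <- ar_psd(noise, order = 16)
  band <- sp$psd[sp$frequencies >= 0.04 & sp$frequencies <= 0.4]
  expect_lt(max(band) / min(band), 3)

  tone <- tone_tachogram(0.25, 30, span = 300)
  tone$rr <- tone$rr + rnorm(length(tone$rr), 0, 2)
  spt <- ar_psd(tone, order = 16)
  expect_lt(abs(spt$frequencies[which.max(spt$psd)] - 0.25), 0.01)

  sp0 <- ar_psd(noise, order = 0)
  x <- hrrkit:::detrend_linear(noise$time, noise$rr)
  expect_equal(unique(round(sp0$psd[-c(1, length(sp0$psd))], 6)),
               round(2 * (sum(x^2) / length(x)) / 4, 6))
})

test_that("lomb_scargle_psd recovers frequency and power on uneven samples", {
  set.seed(5)
  tt <- sort(runif(200, 0, 300))
  x <- 900 + 25 * sin(2 * pi * 0.1 * tt + 1)
  ls <- lomb_scargle_psd(tachogram(tt, x))
  expect_lt(abs(ls$frequencies[which.max(ls$psd)] - 0.1), 1 / 300)

  # A^2/2 band recovery holds under beat-like (jittered) sampling; sparse
  # uniform-random sampling scatters a larger leakage floor into the bands
  tb <- cumsum(runif(420, 0.6, 0.85)); tb <- tb[tb <= 300]
  xb <- 900 + 25 * sin(2 * pi * 0.1 * tb + 1)
  bp <- band_powers(lomb_scargle_psd(tachogram(tb, xb)))
  expect_equal(bp$lf, 25^2 / 2, tolerance = 0.10)

  const <- tachogram(tt, rep(900, length(tt)))
  bpc <- band_powers(lomb_scargle_psd(const))
  expect_lt(bpc$total, 1e-6)

  expect_error(lomb_scargle_psd(tachogram(tt[1:30], x[1:30])),
               "insufficient data")
})

test_that("lomb_scargle on evenly sampled data agrees with welch band powers", {
  two <- tone_tachogram(c(0.1, 0.25), c(20, 30), c(1.2, 0.5))
  bw <- band_powers(welch_psd(two))
  bl <- band_powers(lomb_scargle_psd(tachogram(two$time, two$rr)))
  expect_equal(bl$lf, bw$lf, tolerance = 0.10)
  expect_equal(bl$hf, bw$hf, tolerance = 0.10)
})

test_that("band_powers: bands, normalised units, ratio conventions", {
  tone <- tone_tachogram(0.25, 30)
  bp <- band_powers(welch_psd(tone))
  expect_lt(bp$lf_nu, 0.02)
  expect_gt(bp$hf_nu, 0.98)

  balanced <- tone_tachogram(c(0.1, 0.25), c(30, 30), c(0.3, 1.1))
  bpb <- band_powers(welch_psd(balanced))
  expect_equal(bpb$lf_hf_ratio, 1, tolerance = 0.05)
  expect_equal(bpb$lf_nu, 0.5, tolerance = 0.03)

  # hf = 0 -> ratio reported missing, not infinite
  f <- seq(0, 0.5, by = 0.005)
  p <- ifelse(f >= 0.05 & f <= 0.12, 100, 0)
  sp <- hrrkit:::new_spectral_result(f, p, "welch")
  bp0 <- band_powers(sp)
  expect_true(is.na(bp0$lf_hf_ratio))
  expect_error(hrrkit:::new_spectral_result(f, p - 50, "welch"), "negative")
})

test_that("lf_nu + hf_nu = 1 on every spectrum with positive in-band power", {
  set.seed(77)
  for (i in 1:5) {
    tg <- tone_tachogram(c(0.1, 0.25), runif(2, 5, 40), runif(2, 0, 6),
                         noise_sd = 10)
    for (est in list(welch_psd(tg), ar_psd(tg),
                     lomb_scargle_psd(tachogram(tg$time, tg$rr)))) {
      bp <- band_powers(est)
      expect_equal(bp$lf_nu + bp$hf_nu, 1, tolerance = 1e-12)
      expect_equal(bp$lf_hf_ratio, bp$lf_nu / bp$hf_nu, tolerance = 1e-9)
    }
  }
})

test_that("recovery_spectrum orders LF:HF by construction for all methods", {
  cfg_hf <- fixed_config(lf_amp = 5, hf_amp = 35, noise = 5, seed = 3)
  cfg_lf <- fixed_config(lf_amp = 35, hf_amp = 5, noise = 5, seed = 3)
  s_hf <- generate_subject(cfg_hf, "control", 9)
  s_lf <- generate_subject(cfg_lf, "control", 9)
  for (m in c("welch", "ar", "lomb_scargle")) {
    expect_lt(band <- recovery_spectrum(s_hf, m)$lf_hf_ratio, 1)
    expect_gt(recovery_spectrum(s_lf, m)$lf_hf_ratio, 1)
  }
  # zero modulation, noise only: the normalisation identity still holds
  s0 <- generate_subject(fixed_config(lf_amp = 0, hf_amp = 0, noise = 12),
                         "control", 2)
  bp0 <- recovery_spectrum(s0, "welch")
  expect_equal(bp0$lf_nu + bp0$hf_nu, 1, tolerance = 1e-12)
})
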