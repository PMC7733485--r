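test_that("resampling interpolates constants exactly on a uniform grid", {
  tg <- resample_tachogram(rep(1000, 40), fs = 4)
  expect_true(all(abs(tg$y - 1000) < 1e-9))
  expect_true(all(abs(diff(tg$t) - 0.25) < 1e-12))
  expect_error(resample_tachogram(c(1000, 990, 1000)),
               class = "icehrv_short_series")
})

test_that("resampling a beat-sampled sinusoid matches the analytic curve", {
  nn <- generate_rr_series(tachogram_spec(1000, 0, 30, hf_freq = 0.25,
                                          noise_sd = 0, duration = 600))
  tg <- resample_tachogram(nn$intervals)
  err <- abs(tg$y - (1000 + 30 * sin(2 * pi * 0.25 * tg$t)))
  inner <- tg$t > 2 & tg$t < max(tg$t) - 2
  # cubic-spline interpolation at ~1 s beat spacing: interior error is
  # bounded near (5/384) h^4 A omega^4 ~ 2 ms; edges extrapolate worse
  expect_lt(max(err[inner]), 2)
  expect_lt(max(err), 6)
})

test_that("Welch PSD integrates to the signal variance (Parseval)", {
  set.seed(11)
  ratio <- replicate(20, {
    x <- rnorm(2400)
    sp <- welch_psd(x, fs = 4, detrend = "constant")
    band_power(sp, 0, max(sp$freq)) / stats::var(x)
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)

  # exact Parseval reference carried on the estimate itself
  x <- rnorm(2400)
  sp <- welch_psd(x, fs = 4)
  expect_equal(band_power(sp, 0, max(sp$freq)), sp$segment_power,
               tolerance = 0.01)

  sp0 <- welch_psd(rep(0, 1200), fs = 4)
  expect_true(all(sp0$psd == 0))
  expect_error(welch_psd(rnorm(100), fs = 4), class = "icehrv_short_signal")
})

test_that("a pure sinusoid's band power equals A^2/2", {
  t <- seq(0, 600 - 0.25, by = 0.25)
  for (A in c(5, 20)) {
    sp <- welch_psd(A * sin(2 * pi * 0.25 * t), fs = 4)
    expect_equal(band_power(sp, 0.15, 0.40), A^2 / 2, tolerance = 0.03)
  }
})

test_that("band powers tile the axis and respect the total", {
  nn <- generate_rr_series(tachogram_spec(1000, 20, 30, noise_sd = 5,
                                          duration = 600), seed = 3)
  sp <- welch_psd(resample_tachogram(nn$intervals))
  nyq <- max(sp$freq)
  total <- band_power(sp, 0, nyq)
  parts <- band_power(sp, 0, 0.04) + band_power(sp, 0.04, 0.15) +
    band_power(sp, 0.15, 0.40) + band_power(sp, 0.40, nyq)
  expect_equal(parts, total, tolerance = 1e-9)
  expect_lte(band_power(sp, 0, 0.04) + band_power(sp, 0.04, 0.15) +
               band_power(sp, 0.15, 0.40), total + 1e-9)
  expect_error(band_power(sp, 0.3, 0.1))

  spz <- welch_psd(rep(0, 1200), fs = 4)
  expect_equal(band_power(spz, 0.04, 0.15), 0)
})

test_that("indices recover closed-form sinusoid powers and the nu identities", {
  s <- generate_rr_series(tachogram_spec(1000, 20, 30, 0.1, 0.25,
                                         noise_sd = 0, duration = 600))
  idx <- compute_indices(s$intervals)
  expect_equal(idx$lf, 200, tolerance = 0.10)
  expect_equal(idx$hf, 450, tolerance = 0.10)
  expect_lt(abs(idx$lf_nu - 30.8), 3)
  expect_lt(abs(idx$hf_nu - 69.2), 3)
  expect_lt(abs(idx$hf_peak_hz - 0.25), 0.01)
  expect_equal(idx$lf_nu + idx$hf_nu, 100, tolerance = 1e-9)
  expect_equal(idx$lf_hf, idx$lf / idx$hf, tolerance = 1e-12)
  expect_equal(idx$log_lf_hf, log10(idx$lf) - log10(idx$hf),
               tolerance = 1e-12)
  expect_true(idx$hf_peak_hz >= 0.15 && idx$hf_peak_hz <= 0.40)

  # constant series: HR is exact, spectrum degenerate
  expect_equal(60000 / mean(rep(1000, 700)), 60)
  expect_error(compute_indices(rep(1000, 700)),
               class = "icehrv_degenerate_spectrum")
})

test_that("equal LF and HF content gives symmetric normalized units", {
  s <- generate_rr_series(tachogram_spec(1000, 25, 25, 0.1, 0.25,
                                         noise_sd = 0, duration = 600))
  idx <- compute_indices(s$intervals)
  expect_lt(abs(idx$lf_nu - 50), 2)
  expect_lt(abs(idx$hf_nu - 50), 2)
  expect_lt(abs(idx$log_lf_hf), 0.05)
})

test_that("band-power recovery holds over an amplitude/frequency grid", {
  set.seed(21)
  for (A in c(10, 20, 40)) {
    for (cfg in list(c(0.08, "lf"), c(0.30, "hf"))) {
      f0 <- as.numeric(cfg[1])
      rec <- replicate(5, {
        s <- generate_rr_series(tachogram_spec(
          1000, lf_amp = if (cfg[2] == "lf") A else 0,
          hf_amp = if (cfg[2] == "hf") A else 0,
          lf_freq = if (cfg[2] == "lf") f0 else 0.1,
          hf_freq = if (cfg[2] == "hf") f0 else 0.25,
          noise_sd = 2, duration = 600))
        idx <- compute_indices(s$intervals)
        if (cfg[2] == "lf") idx$lf else idx$hf
      })
      expect_lt(abs(mean(rec) - A^2 / 2) / (A^2 / 2), 0.10)
    }
  }
})

test_that("HF power responds monotonically and quadratically to amplitude", {
  vals <- t(sapply(c(15, 30, 60), function(A) {
    s <- generate_rr_series(tachogram_spec(1000, 20, A, noise_sd = 0,
                                           duration = 600))
    idx <- compute_indices(s$intervals)
    c(hf = idx$hf, hf_nu = idx$hf_nu, log_lf_hf = idx$log_lf_hf)
  }))
  expect_true(all(diff(vals[, "hf"]) > 0))
  expect_true(all(diff(vals[, "hf_nu"]) > 0))
  expect_true(all(diff(vals[, "log_lf_hf"]) < 0))
  # doubling the amplitude quadruples the band power
  expect_equal(unname(vals[2, "hf"] / vals[1, "hf"]), 4, tolerance = 0.05)
  expect_equal(unname(vals[3, "hf"] / vals[2, "hf"]), 4, tolerance = 0.05)
})
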