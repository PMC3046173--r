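test_that("resampling preserves constant series and sinusoidal amplitude", {
  const <- resample_rr(rr_series(rep(800, 50)), fs_i = 4)
  expect_true(all(abs(const$values - 800) < 1e-9))

  # 0.1 Hz modulation of amplitude 30 ms survives interpolation
  t_now <- 0
  x <- numeric(0)
  while (t_now < 120) {
    v <- 800 + 30 * sin(2 * pi * 0.1 * t_now)
    x <- c(x, v)
    t_now <- t_now + v / 1000
  }
  tach <- resample_rr(rr_series(x), fs_i = 4)
  p2p <- max(tach$values) - min(tach$values)
  expect_lt(abs(p2p - 60) / 60, 0.05)

  expect_error(resample_rr(rr_series(c(800, 810, 790))),
               class = "hrvrisk_validation_error")
  expect_error(resample_rr(rr_series(rep(800, 50)), fs_i = 0.5),
               class = "hrvrisk_config_error")
})

test_that("smoothness-priors detrending nulls trends but keeps LF oscillations", {
  ramp <- tachogram(seq(0, 100, length.out = 400), fs_i = 4)
  out <- detrend_sp(ramp, lam = 500)
  expect_lt(sum(out$values^2), 0.01 * sum(ramp$values^2))

  tt <- seq(0, 120 - 0.25, by = 0.25)
  sine <- tachogram(30 * sin(2 * pi * 0.1 * tt), fs_i = 4)
  kept <- detrend_sp(sine, lam = 500)
  expect_gt(sum(kept$values^2) / sum(sine$values^2), 0.90)

  zero <- detrend_sp(tachogram(rep(0, 100), fs_i = 4), lam = 500)
  expect_true(all(zero$values == 0))
})

test_that("AR spectrum integrates to the variance and locates spectral peaks", {
  set.seed(10)
  noise <- tachogram(rnorm(1200, 0, 30), fs_i = 4)
  psd <- ar_psd(noise, p = 16)
  integral <- sum(diff(psd$freqs) * (head(psd$power, -1) +
                                       tail(psd$power, -1)) / 2)
  expect_lt(abs(integral - var(noise$values)) / var(noise$values), 0.10)

  tt <- seq(0, 300 - 0.25, by = 0.25)
  set.seed(11)
  sine <- tachogram(25 * sin(2 * pi * 0.1 * tt) + rnorm(length(tt), 0, 1),
                    fs_i = 4)
  psd2 <- ar_psd(sine, p = 16)
  peak <- psd2$freqs[which.max(psd2$power)]
  expect_gte(peak, 0.08)
  expect_lte(peak, 0.12)

  expect_error(ar_psd(noise, p = 0), class = "hrvrisk_config_error")
  expect_error(ar_psd(tachogram(rnorm(40), 4), p = 16),
               class = "hrvrisk_validation_error")
})

test_that("band powers integrate the canonical partitions", {
  # flat spectrum: band powers proportional to band widths
  flat <- psd_estimate(seq(0, 0.5, length.out = 2048),
                       rep(1, 2048), fs_i = 1)
  bp <- band_powers(flat)
  expect_equal(unname(bp["LFHF"]), 0.11 / 0.25, tolerance = 1e-9)
  expect_equal(unname(bp["VLF"]), 0.04, tolerance = 1e-9)

  # concentrated LF power
  lf_rec <- generate_rr(lf_amp_ms = 30, hf_amp_ms = 1, noise_sd_ms = 1,
                        duration_s = 300, seed = 3)
  bp_lf <- band_powers(ar_psd(detrend_sp(resample_rr(lf_rec))))
  expect_gt(unname(bp_lf["NLF"]), 95)

  # concentrated HF power (0.25 Hz modulation)
  hf_rec <- generate_rr(lf_amp_ms = 1, hf_amp_ms = 30, hf_hz = 0.25,
                        noise_sd_ms = 1, duration_s = 300, seed = 4)
  bp_hf <- band_powers(ar_psd(detrend_sp(resample_rr(hf_rec))))
  expect_gt(unname(bp_hf["NHF"]), 95)

  expect_error(band_powers(psd_estimate(seq(0.1, 0.5, length.out = 100),
                                        rep(1, 100))),
               class = "hrvrisk_validation_error")
})

test_that("band powers are additive and normalized powers sum to 100", {
  for (s in 1:5) {
    set.seed(s)
    tach <- detrend_sp(resample_rr(generate_rr(seed = s, duration_s = 180)))
    psd <- ar_psd(tach)
    bp <- band_powers(psd)
    total <- hrvrisk:::.band_integral(psd, 0, 0.4)
    expect_equal(unname(bp["VLF"] + bp["LF"] + bp["HF"]), total,
                 tolerance = 1e-9)
    expect_identical(unname(bp["NLF"] + bp["NHF"]), 100)
    expect_equal(unname(bp["LFHF"]), unname(bp["LF"] / bp["HF"]))
  }
  # bit-identical determinism of the full spectral path
  rr <- generate_rr(seed = 42, duration_s = 180)
  b1 <- band_powers(ar_psd(detrend_sp(resample_rr(rr))))
  b2 <- band_powers(ar_psd(detrend_sp(resample_rr(rr))))
  expect_identical(b1, b2)
})
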