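test_that("detection scoring implements greedy matching and the Se/Ac formulas", {
  truth <- seq(250, 250 * 100, by = 250)
  # identity
  sc <- score_detection(truth, truth, fs = 250)
  expect_equal(c(sc$FP, sc$FN), c(0L, 0L))
  expect_equal(c(sc$Se, sc$Ac), c(100, 100))
  # 4 missed beats
  sc <- score_detection(truth[-(1:4)], truth, fs = 250)
  expect_equal(sc$Se, 96)
  expect_equal(sc$Ac, 96)
  # all found plus 25 spurious detections between beats
  spurious <- truth[1:25] + 120
  sc <- score_detection(sort(c(truth, spurious)), truth, fs = 250)
  expect_equal(sc$Se, 100)
  expect_equal(sc$Ac, 80)
})

test_that("clean simulated ECG is detected perfectly and noise favors deeper levels", {
  rr <- generate_rr(duration_s = 60, seed = 2)
  ec <- generate_ecg(rr, fs = 250, noise_sd = 0, seed = 2)
  pk <- detect_r_peaks(ec$ecg, level = 4)
  sc <- score_detection(pk, ec$truth)
  expect_equal(c(sc$Se, sc$Ac), c(100, 100))

  # flat signal -> no peaks
  flat <- ecg_record(rep(0, 250 * 10), fs = 250)
  expect_length(detect_r_peaks(flat, level = 4)$indices, 0L)

  # high-frequency noise: the shallow decomposition keeps more noise bands
  ecn <- generate_ecg(rr, fs = 250, noise_sd = 0.08, seed = 11)
  fp1 <- score_detection(detect_r_peaks(ecn$ecg, level = 1), ecn$truth)$FP
  fp4 <- score_detection(detect_r_peaks(ecn$ecg, level = 4), ecn$truth)$FP
  expect_gte(fp1, fp4)

  # too-low sampling rate for the band-pass
  expect_error(detect_r_peaks(ecg_record(rep(0, 100), fs = 30), level = 4),
               class = "hrvrisk_config_error")
})

test_that("RR construction from peaks is exact and sums to the peak span", {
  pk <- r_peak_set(c(0, 250, 500) + 1L, fs = 250)
  expect_equal(rr_from_peaks(pk)$intervals, c(1000, 1000))
  pk2 <- r_peak_set(c(0, 200, 450) + 1L, fs = 250)
  expect_equal(rr_from_peaks(pk2)$intervals, c(800, 1000))
  expect_error(rr_from_peaks(r_peak_set(5L, fs = 250)),
               class = "hrvrisk_empty_error")
  # span identity on a random peak set
  set.seed(4)
  idx <- cumsum(c(1L, sample(150:300, 40, replace = TRUE)))
  pk3 <- r_peak_set(idx, fs = 250)
  expect_equal(sum(rr_from_peaks(pk3)$intervals),
               1000 * (max(idx) - min(idx)) / 250)
})

test_that("the generalized ESD filter matches the brute-force oracle", {
  set.seed(1)
  x <- c(rnorm(59, 800, 20), 2000)
  res <- rosner_filter(rr_series(x), k_max = 5, alpha = 0.05)
  expect_equal(sort(x[res$report$removed_indices]),
               rosner_brute(x, 5, 0.05))
  expect_identical(sort(x[res$report$removed_indices]), 2000)
  expect_length(res$rr$intervals, 59L)

  # several seeded datasets with 0-3 planted outliers
  for (s in 1:6) {
    set.seed(s)
    n_out <- s %% 4
    y <- c(rnorm(80, 800, 15), rep(1800, n_out))
    y <- sample(y)
    res2 <- rosner_filter(rr_series(y), k_max = 8, alpha = 0.05)
    expect_equal(sort(y[res2$report$removed_indices]),
                 rosner_brute(y, 8, 0.05), tolerance = 1e-12)
  }
})

test_that("ESD filter handles degenerate and edge configurations", {
  const <- rr_series(rep(800, 60))
  res <- rosner_filter(const, k_max = 5, alpha = 0.05)
  expect_length(res$report$removed_indices, 0L)
  expect_length(res$report$statistics, 0L)
  expect_equal(res$rr$intervals, const$intervals)

  rnd <- rr_series(800 + abs(rnorm(30, 0, 10)))
  expect_equal(rosner_filter(rnd, k_max = 0)$rr$intervals, rnd$intervals)
  expect_error(rosner_filter(rnd, k_max = 15), class = "hrvrisk_config_error")
  expect_error(rosner_filter(rr_series(rep(800, 5)), k_max = 1),
               class = "hrvrisk_validation_error")
})

test_that("outlier declarations are permutation-invariant and monotone in alpha", {
  set.seed(7)
  base <- c(rnorm(70, 800, 18), 1500, 1650)
  vals_ref <- NULL
  for (s in 1:5) {
    set.seed(s)
    y <- sample(base)
    res <- rosner_filter(rr_series(y), k_max = 6, alpha = 0.05)
    vals <- sort(y[res$report$removed_indices])
    if (is.null(vals_ref)) vals_ref <- vals
    expect_equal(vals, vals_ref)
  }
  # alpha = 0.01 declarations are a subset of alpha = 0.05 declarations
  for (s in 1:5) {
    set.seed(s + 100)
    y <- c(rnorm(60, 800, 20), runif(3, 1200, 1900))
    r01 <- rosner_filter(rr_series(y), k_max = 6, alpha = 0.01)
    r05 <- rosner_filter(rr_series(y), k_max = 6, alpha = 0.05)
    expect_true(all(r01$report$removed_indices %in%
                      r05$report$removed_indices))
  }
})
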