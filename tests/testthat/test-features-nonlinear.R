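test_that("Poincare features satisfy their closed-form special cases", {
  # constant series: no dispersion at all
  pc0 <- poincare_features(rr_series(rep(800, 50)))
  expect_true(all(pc0 == 0))

  # alternating 800/820: all dispersion is beat-to-beat (SD1), none along
  # the identity line (SD2)
  alt <- rr_series(rep(c(800, 820), 50))
  pc <- poincare_features(alt, bin_ms = 0.01)
  expect_equal(unname(pc["SD1"]), 20 / sqrt(2), tolerance = 1e-3)
  expect_equal(unname(pc["SD2"]), 0, tolerance = 1e-9)
  expect_equal(unname(pc["widthL"]), 0)
  expect_equal(unname(pc["widthW"]), 2 * 20 / sqrt(2), tolerance = 1e-3)

  # white noise: SD1 ~ SD2 ~ sigma
  set.seed(9)
  wn <- rr_series(rnorm(400, 800, 25))
  pcw <- poincare_features(wn)
  expect_lt(abs(pcw["SD1"] - 25) / 25, 0.10)
  expect_lt(abs(pcw["SD2"] - 25) / 25, 0.10)

  expect_error(poincare_features(rr_series(c(800, 810))),
               class = "hrvrisk_validation_error")
})

test_that("SD1/SD2 identities against SDSD/SDNN hold to 1e-9 on random series", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(20:200, 1)
    x <- 800 + rnorm(n, 0, runif(1, 5, 60))
    pc <- poincare_features(rr_series(x), bin_ms = 1e-6)
    d <- diff(x)
    sdsd_pop <- sqrt(mean((d - mean(d))^2))
    a <- x[-n]
    b <- x[-1]
    sdnn_lag2 <- (mean((a - mean(a))^2) + mean((b - mean(b))^2)) / 2
    expect_equal(unname(pc["SD1"])^2, sdsd_pop^2 / 2, tolerance = 1e-9)
    expect_equal(unname(pc["SD2"])^2, 2 * sdnn_lag2 - sdsd_pop^2 / 2,
                 tolerance = 1e-9)
  }
})

test_that("optimized ApEn and SmEn equal the brute-force oracles exactly", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(40:120, 1)
    x <- 1000 * runif(n)
    r <- 0.2 * sd(x)
    for (m in 1:4) {
      expect_identical(apen(x, m = m, r = r), apen_brute(x, m, r))
      expect_identical(suppressWarnings(smen(x, m = m, r = r)),
                       smen_brute(x, m, r))
    }
    # the vectorized sweep agrees with the scalar paths
    cf <- complexity_features(x, m_max = 4, k = 0.2)
    for (m in 1:4) {
      expect_identical(unname(cf[paste0("ApEn_m", m)]),
                       apen(x, m = m, r = r))
      expect_identical(unname(cf[paste0("SmEn_m", m)]),
                       suppressWarnings(smen(x, m = m, r = r)))
    }
  }
})

test_that("entropies handle degenerate inputs per their conventions", {
  const <- rr_series(rep(800, 80))
  expect_identical(apen(const, m = 2, r = 1), 0)
  expect_identical(smen(const, m = 2, r = 1), 0)
  expect_identical(apen(const, m = 2), 0)  # default r = k * sd = 0 path

  # no (m+1)-length matches: missing value, not an exception
  set.seed(1)
  x <- cumsum(runif(30, 50, 150))
  expect_warning(v <- smen(x, m = 3, r = 1), "undefined")
  expect_true(is.na(v))

  set.seed(2)
  y <- rnorm(100, 800, 20)
  expect_error(apen(y, m = 2, r = -1), class = "hrvrisk_config_error")
})

test_that("regularity ordering and invariances of the entropy measures", {
  set.seed(3)
  periodic <- rep(c(780, 820), 100)
  noise <- rnorm(200, 800, sd(periodic))
  expect_lt(suppressWarnings(apen(periodic, m = 2, k = 0.2)),
            apen(noise, m = 2, k = 0.2))

  # shift invariance, and scale invariance under r = k * SD
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(150, 800, 30)
    for (fn in list(apen, smen)) {
      v0 <- fn(x, m = 2, k = 0.2)
      expect_equal(fn(x + 123, m = 2, k = 0.2), v0, tolerance = 1e-12)
      expect_equal(fn(x * 3.7, m = 2, k = 0.2), v0, tolerance = 1e-12)
    }
  }

  # SmEn is non-increasing in the tolerance r
  for (s in 1:3) {
    set.seed(s + 50)
    x <- rnorm(200, 800, 25)
    vals <- vapply(c(0.1, 0.15, 0.2, 0.3) * sd(x),
                   function(r) smen(x, m = 2, r = r), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})
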