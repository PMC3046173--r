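test_that("two-sample KS statistic equals the pooled-ECDF scan oracle", {
  for (s in 1:100) {
    set.seed(s)
    na <- sample(5:60, 1)
    nb <- sample(5:60, 1)
    a <- rnorm(na)
    b <- rnorm(nb, mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$D, ks_d_brute(a, b), tolerance = 1e-12)
  }
  # with ties across samples
  set.seed(200)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(2:6, 25, replace = TRUE)
  expect_equal(ks_two_sample(a, b)$D, ks_d_brute(a, b), tolerance = 1e-12)
})

test_that("KS test extremes and power behave canonically", {
  a <- rnorm(20)
  ks <- ks_two_sample(a, a)
  expect_equal(ks$D, 0)
  expect_equal(ks$p, 1)

  expect_equal(ks_two_sample(1:10, 101:110)$D, 1)

  set.seed(5)
  res <- ks_two_sample(rnorm(45), rnorm(45, mean = 1))
  expect_lt(res$p, 0.001)
  # agrees with the reference asymptotic implementation
  ref <- suppressWarnings(stats::ks.test(rnorm(45), rnorm(45, 1),
                                         exact = FALSE))
  set.seed(5)
  res2 <- ks_two_sample(rnorm(45), rnorm(45, mean = 1))
  expect_equal(res$D, res2$D)

  expect_error(ks_two_sample(1:3, 1:10), class = "hrvrisk_validation_error")
})

test_that("normality screening is calibrated and detects gross misfit", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    nc <- normality_check(rnorm(500))
    if (nc$chi2_p > 0.05 && nc$ks1_p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  set.seed(7)
  expo <- normality_check(rexp(500))
  expect_lt(expo$ks1_p, 0.01)
  expect_lt(expo$chi2_p, 0.01)

  expect_true(normality_check(rep(1, 50))$skipped)
  expect_error(normality_check(rnorm(10)), class = "hrvrisk_validation_error")
})

test_that("KS selection recovers a planted group difference and ranks stably", {
  set.seed(1)
  n <- 45
  tab <- data.frame(
    class = rep(c("N", "R"), each = n),
    SDNN = c(rnorm(n, 50, 8), rnorm(n, 25, 5)),   # halved in the risk group
    noise1 = rnorm(2 * n), noise2 = rnorm(2 * n), noise3 = rnorm(2 * n))
  rep1 <- suppressWarnings(select_features(tab, alpha_select = 0.01,
                                           top_k = 2))
  expect_equal(rep1$stats$feature[1], "SDNN")
  expect_true("SDNN" %in% rep1$selected)
  expect_true(all(rep1$stats$D >= 0 & rep1$stats$D <= 1))

  # alpha_select = 0: nothing passes, warning raised
  expect_warning(rep0 <- select_features(tab, alpha_select = 0,
                                         top_k = 2))
  expect_length(rep0$selected, 0L)

  expect_error(select_features(data.frame(class = rep("N", 20), x = 1:20)),
               class = "hrvrisk_label_error")
})

test_that("selection is invariant under monotone per-feature transforms", {
  set.seed(2)
  n <- 40
  tab <- data.frame(class = rep(c("N", "R"), each = n),
                    f1 = c(rnorm(n, 2), rnorm(n, 3)),
                    f2 = abs(c(rnorm(n, 1), rnorm(n, 1.2))) + 0.1,
                    f3 = rnorm(2 * n))
  base <- suppressWarnings(select_features(tab, alpha_select = 0.05,
                                           top_k = 3))
  trans <- tab
  trans$f1 <- 10 * trans$f1 - 4   # affine
  trans$f2 <- log(trans$f2)       # log
  trans$f3 <- exp(trans$f3)       # exp
  mono <- suppressWarnings(select_features(trans, alpha_select = 0.05,
                                           top_k = 3))
  expect_equal(mono$stats[order(mono$stats$feature), c("D", "p")],
               base$stats[order(base$stats$feature), c("D", "p")],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(mono$selected, base$selected)
})

test_that("MinMax normalization learns bounds on the training split only", {
  train <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1))
  test <- data.frame(a = c(8, 2), b = c(5, 0))
  res <- minmax_fit_apply(train, list(test = test))
  expect_equal(res$train$a, c(0, 0.5, 1))
  expect_equal(res$others$test$a, c(1.5, 0))  # out-of-range preserved
  expect_equal(res$train$b, c(0, 0, 0))       # constant -> zeros
  expect_true(res$bounds$constant[res$bounds$feature == "b"])
  expect_equal(res$others$test$b, c(0, 0))

  # endpoints of every non-constant training feature hit 0 and 1
  set.seed(3)
  big <- data.frame(x = rnorm(50), y = runif(50))
  nb <- minmax_fit_apply(big)
  expect_equal(range(nb$train$x), c(0, 1))
  expect_equal(range(nb$train$y), c(0, 1))
})
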