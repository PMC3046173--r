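test_that("confusion-matrix metrics follow their defining identities", {
  m <- metrics_from_confusion(TP = 14, FP = 0, TN = 15, FN = 1)
  expect_equal(round(unname(m), 2), c(93.33, 100.00, 100.00, 93.75, 96.67))

  all50 <- metrics_from_confusion(5, 5, 5, 5)
  expect_true(all(all50 == 50))

  # identities re-derived on random confusion matrices
  set.seed(1)
  for (i in 1:20) {
    cm <- sample(0:30, 4, replace = TRUE) + 1L
    m <- metrics_from_confusion(cm[1], cm[2], cm[3], cm[4])
    expect_equal(unname(m["Se"]), 100 * cm[1] / (cm[1] + cm[4]))
    expect_equal(unname(m["Sp"]), 100 * cm[3] / (cm[3] + cm[2]))
    expect_equal(unname(m["Pp"]), 100 * cm[1] / (cm[1] + cm[2]))
    expect_equal(unname(m["Np"]), 100 * cm[3] / (cm[3] + cm[4]))
    expect_equal(unname(m["Ac"]), 100 * (cm[1] + cm[3]) / sum(cm))
  }
})

test_that("ROC/AUC equals the rank-statistic oracle, including ties", {
  y <- rep(c(1, 0), each = 10)
  expect_equal(roc_auc(c(rep(2, 10), rep(1, 10)), y)$auc, 1.0)
  expect_equal(roc_auc(c(rep(1, 10), rep(2, 10)), y)$auc, 0.0)

  for (s in 1:10) {
    set.seed(s)
    yy <- rbinom(200, 1, 0.5)
    if (length(unique(yy)) < 2) next
    sc <- rnorm(200)
    expect_equal(roc_auc(sc, yy)$auc, auc_rank_oracle(sc, yy),
                 tolerance = 1e-12)
    # heavy ties
    sct <- sample(1:5, 200, replace = TRUE)
    expect_equal(roc_auc(sct, yy)$auc, auc_rank_oracle(sct, yy),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rnorm(5), rep(1, 5)), class = "hrvrisk_label_error")
})

test_that("the LM-trained perceptron has linear and nonlinear capacity", {
  blobs <- make_blobs(n_per = 30, sep = 4, seed = 1)
  mlp <- train_mlp(blobs, hidden = 200, seed = 1)
  rep_tr <- evaluate(mlp, blobs)
  expect_equal(unname(rep_tr$metrics["Ac"]), 100)
  # output is a probability
  sc <- predict(mlp, blobs)
  expect_true(all(sc > 0 & sc < 1))

  xor <- make_xor(n_per = 15, seed = 2)
  mx <- train_mlp(xor, hidden = 50, seed = 3, val_frac = 0)
  expect_equal(unname(evaluate(mx, xor)$metrics["Ac"]), 100)

  # determinism under a fixed seed
  m2 <- train_mlp(blobs, hidden = 200, seed = 1)
  expect_identical(predict(mlp, blobs), predict(m2, blobs))

  bad <- blobs
  bad$f1[1] <- NA
  expect_error(train_mlp(bad), class = "hrvrisk_validation_error")
  expect_error(train_mlp(data.frame(class = rep("N", 10), f = rnorm(10))),
               class = "hrvrisk_label_error")
})

test_that("the RBF network recovers cluster structure and interpolates", {
  blobs <- make_blobs(n_per = 30, sep = 6, seed = 4)
  rbf <- train_rbf(blobs, centers = 2, seed = 1)
  # each k-means center coincides with an empirical blob mean (the blobs
  # are far apart, so k-means partitions exactly by blob)
  emp <- rbind(colMeans(blobs[blobs$class == "N", c("f1", "f2")]),
               colMeans(blobs[blobs$class == "R", c("f1", "f2")]))
  d <- as.matrix(dist(rbind(rbf$centers, emp)))[1:2, 3:4]
  expect_lt(min(d[1, ]) + min(d[2, ]), 0.1)
  expect_equal(unname(evaluate(rbf, blobs)$metrics["Ac"]), 100)

  # centers = n_train: interpolation regime
  small <- make_blobs(n_per = 8, sep = 3, seed = 5)
  rbf_n <- train_rbf(small, centers = nrow(small), seed = 1)
  expect_equal(unname(evaluate(rbf_n, small)$metrics["Ac"]), 100)

  # determinism
  r2 <- train_rbf(blobs, centers = 2, seed = 1)
  expect_identical(predict(rbf, blobs), predict(r2, blobs))
})

test_that("SVM schemes separate blobs and report their support vectors", {
  blobs <- make_blobs(n_per = 30, sep = 5, seed = 6)
  test <- make_blobs(n_per = 15, sep = 5, seed = 7)
  svm_l <- train_svm(blobs, "linear", C = 1)
  expect_equal(unname(evaluate(svm_l, test)$metrics["Ac"]), 100)
  expect_lt(svm_l$n_support_vectors, nrow(blobs) / 2)
  expect_lte(svm_l$n_support_vectors, nrow(blobs))

  # heuristic grid search for the nonlinear kernels
  for (kern in c("polynomial", "rbf")) {
    fit <- train_svm(blobs, kern, seed = 1)
    expect_gte(unname(evaluate(fit, test)$metrics["Ac"]), 90)
    expect_lte(fit$n_support_vectors, nrow(blobs))
  }

  # contradictory duplicated points cannot all be fitted
  contra <- data.frame(class = rep(c("N", "R"), 10),
                       f1 = rep(1, 20), f2 = rep(2, 20))
  sc <- train_svm(contra, "linear", C = 1)
  expect_lte(unname(evaluate(sc, contra)$metrics["Ac"]), 50)

  expect_error(train_svm(data.frame(class = rep("R", 8), f = rnorm(8)),
                         "linear"),
               class = "hrvrisk_label_error")
})

test_that("the split protocol stratifies 2/3-1/3 and is seed-reproducible", {
  co <- generate_cohort(cohort_spec(n_per_class = 45, duration_s = 120,
                                    seed = 3))
  # lightweight stand-in features keep this protocol test fast
  set.seed(1)
  tab <- data.frame(id = names(co$labels), class = unname(co$labels),
                    SDNN = vapply(co$series,
                                  function(s) sd(s$intervals), numeric(1)),
                    f2 = rnorm(90), f3 = rnorm(90), f4 = rnorm(90),
                    f5 = rnorm(90), f6 = rnorm(90))
  cv <- cross_validate(tab, scheme = "svm-linear", top_k = 5, seed = 9)
  cm <- cv$reports[[1]]$confusion
  expect_equal(sum(cm), 30)                      # 15 + 15 test records
  expect_equal(unname(cm["TP"] + cm["FN"]), 15)  # risk side
  expect_equal(unname(cm["TN"] + cm["FP"]), 15)  # normal side

  cv2 <- cross_validate(tab, scheme = "svm-linear", top_k = 5, seed = 9)
  expect_identical(cv$summary, cv2$summary)
  expect_identical(cv$selected, cv2$selected)

  expect_error(cross_validate(tab, scheme = "nonsense"),
               class = "hrvrisk_config_error")
  tiny <- tab[c(1, 2, 46), ]
  expect_error(cross_validate(tiny, scheme = "svm-linear"),
               class = "hrvrisk_validation_error")
})
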