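# shared input handling: data frame with a `class` column ("N"/"R", risk
# "R" is the positive class) and numeric feature columns
.class_xy <- function(train) {
  stopifnot(is.data.frame(train), "class" %in% names(train))
  feats <- setdiff(names(train), c("id", "class"))
  x <- as.matrix(train[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    hrv_stop("non-finite feature values", class = "hrvrisk_validation_error")
  cls <- as.character(train$class)
  if (length(unique(cls)) < 2L)
    hrv_stop("training set contains a single class",
             class = "hrvrisk_label_error")
  list(x = x, y = as.numeric(cls == "R"), features = feats)
}

# forward pass of the 3-layer perceptron
.mlp_forward <- function(x, w1, b1, w2, b2) {
  z <- tanh(sweep(x %*% w1, 2L, b1, `+`))
  list(z = z, out = plogis(drop(z %*% w2) + b2))
}

# one Levenberg-Marquardt fit from a given initialization; the damped step
# is solved through the SVD of the (n x p) Jacobian, which keeps the cost
# linear in the parameter count for the small-n training sets used here
.mlp_lm_fit <- function(x, y, hidden, max_iter, xval = NULL, yval = NULL,
                        patience = 6L) {
  d <- ncol(x)
  w1 <- matrix(runif(d * hidden, -1, 1) / sqrt(d), d, hidden)
  b1 <- runif(hidden, -0.1, 0.1)
  w2 <- runif(hidden, -1, 1) / sqrt(hidden)
  b2 <- 0
  lambda <- 1e-2
  fwd <- .mlp_forward(x, w1, b1, w2, b2)
  sse <- sum((y - fwd$out)^2)
  best_val <- Inf
  best <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  bad_checks <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - fwd$out
    s <- fwd$out * (1 - fwd$out)           # d out / d net
    tt <- (s * (1 - fwd$z^2)) * rep(w2, each = nrow(x))  # n x hidden
    j_w1 <- tt[, rep(seq_len(hidden), each = d), drop = FALSE] *
      x[, rep(seq_len(d), hidden), drop = FALSE]
    jac <- cbind(j_w1, tt, s * fwd$z, s)
    sv <- svd(jac)
    utr <- crossprod(sv$u, r)
    improved <- FALSE
    for (tries in seq_len(25L)) {
      step <- drop(sv$v %*% (sv$d / (sv$d^2 + lambda) * utr))
      nw1 <- w1 + matrix(step[seq_len(d * hidden)], d, hidden)
      nb1 <- b1 + step[d * hidden + seq_len(hidden)]
      nw2 <- w2 + step[(d + 1L) * hidden + seq_len(hidden)]
      nb2 <- b2 + step[(d + 2L) * hidden + 1L]
      nfwd <- .mlp_forward(x, nw1, nb1, nw2, nb2)
      nsse <- sum((y - nfwd$out)^2)
      if (is.finite(nsse) && nsse < sse) {
        improved <- TRUE
        rel <- (sse - nsse) / max(sse, 1e-12)
        w1 <- nw1; b1 <- nb1; w2 <- nw2; b2 <- nb2
        fwd <- nfwd
        sse <- nsse
        lambda <- max(lambda / 3, 1e-12)
        if (rel < 1e-10) improved <- FALSE  # converged: exit after checks
        break
      }
      lambda <- lambda * 5
      if (lambda > 1e12) break
    }
    if (!is.null(xval)) {
      vout <- .mlp_forward(xval, w1, b1, w2, b2)$out
      vmse <- mean((yval - vout)^2)
      if (vmse < best_val - 1e-12) {
        best_val <- vmse
        best <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (bad_checks >= patience) break
      }
    }
    if (!improved || lambda > 1e12) break
  }
  if (is.null(xval)) best <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  c(best, list(sse = sse, val = best_val))
}

#' Train the multilayer perceptron classifier
#'
#' Three-layer network (inputs, `hidden` tanh units, one logistic output in
#' (0, 1)) trained by Levenberg-Marquardt least squares on the 0/1 class
#' labels (risk = 1). A fraction of the training data can be held out for
#' early stopping on rising validation error; a small number of random
#' restarts guards against poor initializations. Deterministic for a fixed
#' seed.
#'
#' @param train Data frame with a `class` column (`"N"`/`"R"`) and numeric
#'   feature columns; normalize first (see [minmax_fit_apply]).
#' @param hidden Hidden-layer width (default 200).
#' @param seed Integer seed.
#' @param max_iter Maximum LM iterations (default 200).
#' @param val_frac Fraction held out for early stopping (0 disables).
#' @param patience Early-stopping patience in validation checks.
#' @param restarts Random restarts, best training SSE (or validation error)
#'   kept.
#' @return Object of class `hrv_mlp` with a [predict][predict.hrv_mlp]
#'   method returning scores in (0, 1); decision threshold 0.5.
#' @export
train_mlp <- function(train, hidden = 200L, seed = 1L, max_iter = 200L,
                      val_frac = 0.2, patience = 6L, restarts = 2L) {
  dat <- .class_xy(train)
  if (hidden < 1L)
    hrv_stop("'hidden' must be >= 1", class = "hrvrisk_config_error")
  set.seed(seed)
  n <- nrow(dat$x)
  xval <- NULL
  yval <- NULL
  xtr <- dat$x
  ytr <- dat$y
  if (val_frac > 0) {
    # stratified holdout; skipped when either class would drop below 2
    idx0 <- which(dat$y == 0)
    idx1 <- which(dat$y == 1)
    nv0 <- floor(val_frac * length(idx0))
    nv1 <- floor(val_frac * length(idx1))
    if (nv0 >= 1L && nv1 >= 1L &&
        length(idx0) - nv0 >= 2L && length(idx1) - nv1 >= 2L) {
      vid <- c(sample(idx0, nv0), sample(idx1, nv1))
      xval <- dat$x[vid, , drop = FALSE]
      yval <- dat$y[vid]
      xtr <- dat$x[-vid, , drop = FALSE]
      ytr <- dat$y[-vid]
    }
  }
  best <- NULL
  for (rs in seq_len(max(1L, restarts))) {
    fit <- .mlp_lm_fit(xtr, ytr, hidden, max_iter, xval, yval, patience)
    score <- if (!is.null(xval)) fit$val else fit$sse
    if (is.null(best) || score < best$score)
      best <- c(fit, list(score = score))
  }
  structure(list(w1 = best$w1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
                 features = dat$features, hidden = hidden, seed = seed,
                 threshold = 0.5),
            class = "hrv_mlp")
}

#' @export
predict.hrv_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  .mlp_forward(x, object$w1, object$b1, object$w2, object$b2)$out
}

#' Train the radial basis function network classifier
#'
#' Hidden centers by k-means on the training features (run to
#' stabilization), Gaussian width per center set to its influence radius --
#' the distance to the nearest other center (`width_rule = "nearest"`,
#' default) or the mean pairwise center distance (`"mean"`). The linear
#' output layer is fitted by least squares on the 0/1 labels; decision
#' threshold 0.5.
#'
#' @param train As in [train_mlp].
#' @param centers Number of hidden units (default 3).
#' @param seed Integer seed (k-means initialization).
#' @param width_rule `"nearest"` or `"mean"`.
#' @return Object of class `hrv_rbf`.
#' @export
train_rbf <- function(train, centers = 3L, seed = 1L,
                      width_rule = c("nearest", "mean")) {
  dat <- .class_xy(train)
  width_rule <- match.arg(width_rule)
  n <- nrow(dat$x)
  if (centers < 1L || centers > n)
    hrv_stop("'centers' must be in 1..n_train",
             class = "hrvrisk_config_error")
  set.seed(seed)
  cx <- unique(dat$x)
  if (centers >= nrow(cx)) {
    km_centers <- cx
  } else {
    km <- kmeans(dat$x, centers = centers, nstart = 10L, iter.max = 100L)
    km_centers <- km$centers
    if (any(km$size == 0)) {
      # re-seed empty clusters from the farthest points
      far <- order(-apply(as.matrix(stats::dist(dat$x)), 1L, max))
      km_centers[km$size == 0, ] <- dat$x[far[seq_len(sum(km$size == 0))], ]
    }
  }
  kc <- nrow(km_centers)
  if (kc > 1L) {
    dd <- as.matrix(stats::dist(km_centers))
    diag(dd) <- Inf
    sig <- switch(width_rule,
                  nearest = apply(dd, 1L, min),
                  mean = rep(mean(dd[is.finite(dd)]), kc))
  } else {
    sig <- sqrt(mean(rowSums(sweep(dat$x, 2L, km_centers[1L, ])^2)))
  }
  sig[!is.finite(sig) | sig == 0] <-
    max(mean(sig[is.finite(sig) & sig > 0]), 1e-6)
  phi <- .rbf_design(dat$x, km_centers, sig)
  w <- qr.coef(qr(cbind(1, phi)), dat$y)
  w[!is.finite(w)] <- 0
  structure(list(centers = km_centers, sigma = sig, w = w,
                 features = dat$features, threshold = 0.5, seed = seed),
            class = "hrv_rbf")
}

.rbf_design <- function(x, centers, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  exp(-sweep(d2, 2L, 2 * sigma^2, `/`))
}

#' @export
predict.hrv_rbf <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  drop(cbind(1, .rbf_design(x, object$centers, object$sigma)) %*% object$w)
}

#' Train a support vector machine classifier
#'
#' Soft-margin SVM (libsvm through e1071) with a linear, polynomial or
#' Gaussian RBF kernel. When `C` (and `degree`/`gamma` for the nonlinear
#' kernels) are not given, they are set heuristically by a small grid
#' search -- `C` in {0.1, 1, 10, 100} crossed with degree {2, 3} or gamma
#' {0.01, 0.1, 1} -- scored by stratified 3-fold cross-validation on the
#' training split; the linear kernel defaults to `C = 1`.
#'
#' @param train As in [train_mlp].
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param C Soft-margin penalty (> 0), or NULL for the heuristic search.
#' @param degree Polynomial degree, or NULL.
#' @param gamma RBF kernel width, or NULL.
#' @param seed Integer seed (fold assignment).
#' @return Object of class `hrv_svm`; `n_support_vectors` reports the
#'   support-vector count.
#' @export
train_svm <- function(train, kernel = c("linear", "polynomial", "rbf"),
                      C = NULL, degree = NULL, gamma = NULL, seed = 1L) {
  dat <- .class_xy(train)
  kernel <- match.arg(kernel)
  ek <- switch(kernel, linear = "linear", polynomial = "polynomial",
               rbf = "radial")
  y <- factor(ifelse(dat$y == 1, "R", "N"), levels = c("N", "R"))
  fit_one <- function(x, yy, cost, dg, gm) {
    if (!is.null(dg) && is.na(dg)) dg <- NULL
    if (!is.null(gm) && is.na(gm)) gm <- NULL
    e1071::svm(x, yy, kernel = ek, cost = cost,
               degree = dg %||% 3, gamma = gm %||% (1 / ncol(x)),
               scale = FALSE, probability = FALSE)
  }
  if (!is.null(C)) stopifnot_scalar_num(C, "C", lower = 0, strict_lower = TRUE)
  if (!is.null(degree) && degree < 1)
    hrv_stop("'degree' must be >= 1", class = "hrvrisk_config_error")
  if (!is.null(gamma) && gamma <= 0)
    hrv_stop("'gamma' must be > 0", class = "hrvrisk_config_error")
  need_search <- (kernel != "linear" && (is.null(C) || is.null(degree) &&
                    kernel == "polynomial" || is.null(gamma) &&
                    kernel == "rbf"))
  if (kernel == "linear") {
    C <- C %||% 1
    pars <- data.frame(C = C, degree = NA, gamma = NA)
  } else if (need_search) {
    cs <- if (is.null(C)) c(0.1, 1, 10, 100) else C
    if (kernel == "polynomial") {
      grid <- expand.grid(C = cs, degree = if (is.null(degree)) c(2, 3)
                          else degree, gamma = NA)
    } else {
      grid <- expand.grid(C = cs, degree = NA,
                          gamma = if (is.null(gamma)) c(0.01, 0.1, 1)
                          else gamma)
    }
    set.seed(seed)
    folds <- integer(nrow(dat$x))
    for (cl in unique(y)) {
      ii <- which(y == cl)
      folds[ii] <- sample(rep_len(1:3, length(ii)))
    }
    cv_err <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(1:3, function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        fit <- fit_one(dat$x[tr, , drop = FALSE], y[tr], grid$C[g],
                       grid$degree[g], grid$gamma[g])
        mean(predict(fit, dat$x[!tr, , drop = FALSE]) != y[!tr])
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    pars <- grid[which.min(cv_err), , drop = FALSE]
  } else {
    pars <- data.frame(C = C, degree = degree %||% NA, gamma = gamma %||% NA)
  }
  fit <- fit_one(dat$x, y, pars$C,
                 if (is.na(pars$degree)) NULL else pars$degree,
                 if (is.na(pars$gamma)) NULL else pars$gamma)
  # orientation of libsvm decision values: positive side = first label seen
  dv <- attr(predict(fit, dat$x, decision.values = TRUE), "decision.values")
  flip <- if (grepl("^R/", colnames(dv)[1L])) 1 else -1
  structure(list(fit = fit, flip = flip, features = dat$features,
                 kernel = kernel, params = pars,
                 n_support_vectors = fit$tot.nSV, threshold = 0,
                 seed = seed),
            class = "hrv_svm")
}

#' @export
predict.hrv_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  dv <- attr(predict(object$fit, x, decision.values = TRUE),
             "decision.values")
  object$flip * drop(dv)
}

#' Performance metrics from a confusion matrix
#'
#' @param TP,FP,TN,FN Confusion-matrix counts (risk = positive class).
#' @return Named vector: `Se = 100 TP/(TP+FN)`, `Sp = 100 TN/(TN+FP)`,
#'   `Pp = 100 TP/(TP+FP)`, `Np = 100 TN/(TN+FN)`,
#'   `Ac = 100 (TP+TN)/total`.
#' @export
metrics_from_confusion <- function(TP, FP, TN, FN) {
  c(Se = 100 * TP / (TP + FN), Sp = 100 * TN / (TN + FP),
    Pp = 100 * TP / (TP + FP), Np = 100 * TN / (TN + FN),
    Ac = 100 * (TP + TN) / (TP + FP + TN + FN))
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores; the AUC by
#' trapezoidal integration equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (ties counted 1/2).
#'
#' @param scores Continuous classifier scores, larger = more risk-like.
#' @param labels Class labels (`"R"` positive) or 0/1.
#' @return List with `points` (data frame FPR, TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels != 0)
       else as.integer(as.character(labels) == "R")
  if (!any(y == 1) || !any(y == 0))
    hrv_stop("both classes must be present for an ROC curve",
             class = "hrvrisk_label_error")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  last_of_tie <- c(diff(ss) != 0, TRUE)
  tpr <- c(0, tp[last_of_tie] / sum(y))
  fpr <- c(0, fp[last_of_tie] / sum(1 - y))
  auc <- trapz(fpr, tpr)
  list(points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Evaluate a trained classifier on a labeled test table
#'
#' Predicts continuous scores, thresholds them (0.5 for the networks, 0 for
#' the SVM margin), builds the confusion matrix with cardiovascular risk
#' (`"R"`) as the positive class, and attaches the five performance
#' measures, the ROC points and the AUC.
#'
#' @param model A `hrv_mlp`, `hrv_rbf` or `hrv_svm` model.
#' @param test Data frame with `class` and the model's features.
#' @return Object of class `classifier_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(is.data.frame(test), "class" %in% names(test))
  scores <- predict(model, test)
  truth <- as.character(test$class) == "R"
  pred <- scores >= model$threshold
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth)
  roc <- if (any(truth) && any(!truth)) roc_auc(scores, test$class)
         else list(points = NULL, auc = NA_real_)
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 metrics = metrics_from_confusion(tp, fp, tn, fn),
                 roc = roc$points, auc = roc$auc,
                 n_support_vectors = model$n_support_vectors),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<classifier_report: TP %d FP %d TN %d FN %d | %s | AUC %.4f>\n",
              cm["TP"], cm["FP"], cm["TN"], cm["FN"],
              paste(sprintf("%s %.2f", names(x$metrics), x$metrics),
                    collapse = " "),
              x$auc))
  invisible(x)
}

# scheme name -> trainer
.scheme_trainer <- function(scheme, seed, hidden = 200L, centers = 3L) {
  switch(scheme,
         "mlp" = function(tr) train_mlp(tr, hidden = hidden, seed = seed),
         "rbf" = function(tr) train_rbf(tr, centers = centers, seed = seed),
         "svm-linear" = function(tr) train_svm(tr, "linear", seed = seed),
         "svm-poly" = function(tr) train_svm(tr, "polynomial", seed = seed),
         "svm-rbf" = function(tr) train_svm(tr, "rbf", seed = seed),
         hrv_stop("unknown classifier scheme '", scheme, "'",
                  class = "hrvrisk_config_error"))
}

#' Stratified split / repeated cross-validation protocol
#'
#' Repeats the study protocol: a stratified random two-thirds/one-third
#' train/test split (a balanced 45+45 cohort yields 30+30 training and
#' 15+15 test records), KS-based top-`top_k` feature selection and MinMax
#' normalization both fitted on the training split, classifier training,
#' and evaluation on the held-out third.
#'
#' @param table Feature table from [cohort_features] (`id`, `class`,
#'   features).
#' @param scheme One of `"mlp"`, `"rbf"`, `"svm-linear"`, `"svm-poly"`,
#'   `"svm-rbf"`.
#' @param top_k Features kept by KS rank (default 5).
#' @param seed Integer seed; repeat `r` uses `seed + r - 1`.
#' @param repeats Number of random splits (default 1, the single-split
#'   protocol).
#' @param train_frac Training fraction (default 2/3).
#' @param alpha_select Selection threshold inside each split; the default 1
#'   keeps the pure top-`top_k` KS ranking so a model can always be fitted.
#' @param hidden,centers Network sizes passed through to the trainers.
#' @return Object of class `cv_result`: per-repeat `reports`, the selected
#'   features per repeat, and a `summary` data frame of mean and sd for
#'   Se/Sp/Pp/Np/Ac and AUC over repeats.
#' @export
cross_validate <- function(table, scheme = "mlp", top_k = 5L, seed = 1L,
                           repeats = 1L, train_frac = 2 / 3,
                           alpha_select = 1, hidden = 200L, centers = 3L) {
  stopifnot(is.data.frame(table), "class" %in% names(table))
  trainer_check <- .scheme_trainer(scheme, seed)  # fail fast on bad scheme
  classes <- unique(table$class)
  if (length(classes) != 2L)
    hrv_stop("cohort must contain two classes", class = "hrvrisk_label_error")
  n_cl <- table(table$class)
  if (any(floor(train_frac * n_cl) < 2) || any(n_cl - floor(train_frac * n_cl) < 1))
    hrv_stop("cohort too small for a stratified split",
             class = "hrvrisk_validation_error")
  # features with non-finite values (e.g. undefined SmEn at large m) cannot
  # enter a model; drop them from the candidate pool up front
  feats <- setdiff(names(table), c("id", "class"))
  ok <- vapply(feats, function(f) all(is.finite(table[[f]])), logical(1))
  pool <- table[, c(intersect(c("id", "class"), names(table)), feats[ok])]
  reports <- vector("list", repeats)
  selected <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    tr_idx <- unlist(lapply(classes, function(cl) {
      ii <- which(pool$class == cl)
      sample(ii, floor(train_frac * length(ii)))
    }))
    train <- pool[tr_idx, , drop = FALSE]
    test <- pool[-tr_idx, , drop = FALSE]
    sel <- suppressWarnings(
      select_features(train, alpha_select = alpha_select, top_k = top_k))
    keep <- sel$selected
    if (!length(keep))
      hrv_stop("no features selected; raise alpha_select or top_k",
               class = "hrvrisk_config_error")
    cols <- c("class", keep)
    nm <- minmax_fit_apply(train[, cols], list(test = test[, cols]))
    model <- .scheme_trainer(scheme, seed + r - 1L, hidden, centers)(nm$train)
    reports[[r]] <- evaluate(model, nm$others$test)
    selected[[r]] <- keep
  }
  met <- t(vapply(reports, function(rp) c(rp$metrics, AUC = rp$auc),
                  numeric(6)))
  structure(list(scheme = scheme, reports = reports, selected = selected,
                 summary = data.frame(metric = colnames(met),
                                      mean = colMeans(met),
                                      sd = apply(met, 2L, sd),
                                      row.names = NULL)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s, %d repeat(s)>\n", x$scheme,
              length(x$reports)))
  print(x$summary, digits = 4)
  invisible(x)
}
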