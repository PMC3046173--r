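#' Normality screening for one feature sample
#'
#' Pearson chi-square goodness-of-fit against a fitted Normal (equal-
#' probability bins merged so every expected count is at least 5, two
#' estimated parameters deducted from the degrees of freedom) and a
#' one-sample Kolmogorov-Smirnov test against `Normal(mean, sd)` of the
#' sample. Used to justify distribution-free feature screening.
#'
#' @param values Numeric sample, `n >= 20`.
#' @return List with `chi2_p`, `ks1_p` and `skipped` (TRUE for
#'   zero-variance samples, where both tests are undefined).
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 20L)
    hrv_stop("need at least 20 observations for the chi-square binning",
             class = "hrvrisk_validation_error")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    return(list(chi2_p = NA_real_, ks1_p = NA_real_, skipped = TRUE))
  k <- max(4L, min(20L, floor(n / 5)))
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1L), mean = m, sd = s)
  breaks[1L] <- -Inf
  breaks[k + 1L] <- Inf
  obs <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                  nbins = k)
  expected <- n / k
  stat <- sum((obs - expected)^2 / expected)
  chi2_p <- stats::pchisq(stat, df = k - 3L, lower.tail = FALSE)
  ks1_p <- suppressWarnings(ks.test(values, "pnorm", m, s)$p.value)
  list(chi2_p = chi2_p, ks1_p = ks1_p, skipped = FALSE)
}

# upper tail of the Kolmogorov distribution, Q(lambda) = P(sup > lambda)
.kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  kk <- 1:100
  q <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))
  min(1, max(0, q))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs (computed by
#' a pooled-sort scan); the p-value uses the asymptotic Kolmogorov
#' distribution at the effective sample size `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples of at least 5 observations each.
#' @return List with the statistic `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 5L || length(b) < 5L)
    hrv_stop("both samples need at least 5 observations",
             class = "hrvrisk_validation_error")
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  steps <- cumsum(ifelse(ord <= na, 1 / na, -1 / nb))
  # at tied pooled values only the final cumulative height counts
  vals <- pooled[ord]
  last_of_run <- c(diff(vals) != 0, TRUE)
  d <- max(abs(steps[last_of_run]))
  ne <- na * nb / (na + nb)
  list(D = d, p = .kolmogorov_q(sqrt(ne) * d))
}

#' KS-test feature selection
#'
#' Runs the two-sample KS test per feature between the two label groups,
#' keeps features with `p < alpha_select`, ranks them by ascending p-value
#' (ties broken by the stable global column order) and returns the first
#' `top_k`.
#'
#' @param table Data frame with a two-level `class` column and numeric
#'   feature columns (an `id` column is ignored).
#' @param alpha_select Selection threshold (default 0.01, the stricter of
#'   the two screening levels).
#' @param alpha_significant Reporting threshold (default 0.05).
#' @param top_k Number of features to return.
#' @return Object of class `selection_report`: data frame `stats`
#'   (feature, D, p, significant, rank), the thresholds, and `selected`
#'   (ordered feature names, at most `top_k`).
#' @export
select_features <- function(table, alpha_select = 0.01,
                            alpha_significant = 0.05, top_k = 5L) {
  stopifnot(is.data.frame(table), "class" %in% names(table))
  if (top_k < 1L)
    hrv_stop("'top_k' must be >= 1", class = "hrvrisk_config_error")
  groups <- unique(table$class)
  if (length(groups) != 2L)
    hrv_stop("feature table must contain exactly two label groups",
             class = "hrvrisk_label_error")
  feats <- setdiff(names(table), c("id", "class"))
  ga <- table$class == groups[1L]
  res <- lapply(feats, function(f) {
    va <- table[[f]][ga]
    vb <- table[[f]][!ga]
    va <- va[is.finite(va)]
    vb <- vb[is.finite(vb)]
    if (length(va) < 5L || length(vb) < 5L)
      return(list(D = NA_real_, p = 1))  # undefined feature: never selected
    ks_two_sample(va, vb)
  })
  stats_df <- data.frame(
    feature = feats,
    D = vapply(res, `[[`, numeric(1), "D"),
    p = vapply(res, `[[`, numeric(1), "p"))
  stats_df$significant <- stats_df$p < alpha_significant
  ord <- order(stats_df$p, seq_len(nrow(stats_df)))
  stats_df <- stats_df[ord, , drop = FALSE]
  stats_df$rank <- seq_len(nrow(stats_df))
  row.names(stats_df) <- NULL
  passing <- stats_df$feature[stats_df$p < alpha_select]
  if (length(passing) < top_k)
    hrv_warn(sprintf("only %d of the requested %d features pass p < %g",
                     length(passing), top_k, alpha_select))
  structure(list(stats = stats_df, alpha_select = alpha_select,
                 alpha_significant = alpha_significant,
                 selected = head(passing, top_k)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %d features tested, %d selected at p < %g>\n",
              nrow(x$stats), length(x$selected), x$alpha_select))
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' MinMax normalization fitted on the training split
#'
#' Learns per-feature bounds on the training table only and maps
#' `x' = (x - min) / (max - min)`; the same bounds are applied unchanged to
#' any other tables, whose values may therefore fall outside `[0, 1]`.
#' Constant training features map to 0 and are flagged.
#'
#' @param train Data frame of numeric features (plus optional `id`/`class`
#'   columns, passed through untouched).
#' @param others Optional named list of tables to transform with the
#'   training bounds.
#' @return List with `train`, `others` (both transformed) and `bounds`
#'   (feature, min, max, constant flag).
#' @export
minmax_fit_apply <- function(train, others = list()) {
  stopifnot(is.data.frame(train), nrow(train) > 0L)
  feats <- setdiff(names(train), c("id", "class"))
  bounds <- data.frame(
    feature = feats,
    min = vapply(feats, function(f) min(train[[f]]), numeric(1)),
    max = vapply(feats, function(f) max(train[[f]]), numeric(1)))
  bounds$constant <- bounds$max == bounds$min
  apply_bounds <- function(tab) {
    for (i in seq_along(feats)) {
      f <- feats[i]
      tab[[f]] <- if (bounds$constant[i]) {
        rep(0, nrow(tab))
      } else {
        (tab[[f]] - bounds$min[i]) / (bounds$max[i] - bounds$min[i])
      }
    }
    tab
  }
  list(train = apply_bounds(train),
       others = lapply(others, apply_bounds),
       bounds = bounds)
}
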