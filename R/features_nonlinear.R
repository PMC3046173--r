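#' Poincare-map features
#'
#' Plots each interval against the next, rotates the point cloud by pi/4
#' onto the identity-line axis `u = (x[n+1] + x[n]) / sqrt(2)` and its
#' perpendicular `v = (x[n+1] - x[n]) / sqrt(2)`, and measures:
#' \describe{
#'   \item{SD1}{population sd of `v` -- short-term (beat-to-beat)
#'     dispersion}
#'   \item{SD2}{population sd of `u` -- long-term dispersion along the
#'     identity line}
#'   \item{widthNN, widthW, widthL}{widths of the NN-interval, width (`v`)
#'     and length (`u`) histograms: the range rounded up to a whole number
#'     of bins of `bin_ms`}
#' }
#' The population-sd convention makes the closed-form identities
#' `SD1^2 = SDSD_pop^2 / 2` and `SD2^2 = 2 SDNN_lag^2 - SDSD_pop^2 / 2`
#' exact, where `SDNN_lag^2` is the mean of the population variances of the
#' two lagged coordinate sets.
#'
#' @param rr An [rr_series] with at least 3 intervals.
#' @param bin_ms Histogram bin width in ms; 7.8125 ms (1/128 s) is the
#'   conventional HRV histogram resolution.
#' @return Named numeric vector `SD1, SD2, widthNN, widthW, widthL` (ms).
#' @export
poincare_features <- function(rr, bin_ms = 7.8125) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 3L)
    hrv_stop("need at least 3 intervals for Poincare features",
             class = "hrvrisk_validation_error")
  stopifnot_scalar_num(bin_ms, "bin_ms", lower = 0, strict_lower = TRUE)
  n <- length(x)
  a <- x[-n]
  b <- x[-1L]
  u <- (b + a) / sqrt(2)
  v <- (b - a) / sqrt(2)
  binned_width <- function(z) {
    r <- max(z) - min(z)
    if (r == 0) 0 else ceiling(r / bin_ms) * bin_ms
  }
  c(SD1 = pop_sd(v), SD2 = pop_sd(u),
    widthNN = binned_width(a), widthW = binned_width(v),
    widthL = binned_width(u))
}

# Chebyshev template-match matrices B_m[i, j] = 1 iff the m-length windows
# starting at i and j stay within r of each other; shared by ApEn and SmEn
.template_matches <- function(x, m, r) {
  n <- length(x)
  l1 <- abs(outer(x, x, `-`)) <= r
  b <- l1
  if (m > 1L) {
    for (o in seq_len(m - 1L)) {
      nm <- n - o
      b <- b[seq_len(nm), seq_len(nm), drop = FALSE] &
        l1[(o + 1L):n, (o + 1L):n, drop = FALSE]
    }
  }
  b
}

.resolve_r <- function(x, r, k) {
  if (!is.null(r)) return(r)
  k * sd(x)
}

#' Approximate entropy of an RR series
#'
#' Standard Pincus ApEn: `Phi^m(r) - Phi^(m+1)(r)` with Chebyshev template
#' distance, self-matches included, and
#' `Phi^m = mean_i log(C_i^m(r))` where `C_i^m` is the fraction of
#' templates within `r` of template `i`. Low values indicate regular,
#' predictable dynamics.
#'
#' @param rr An [rr_series] (or bare numeric vector of intervals).
#' @param m Embedding (template) length, typically 1--4.
#' @param r Tolerance in ms; default `k * sd(series)`.
#' @param k Tolerance factor when `r` is not given; the recommended range
#'   is 0.1--0.2 times the series sd.
#' @return Approximate entropy (nats).
#' @export
apen <- function(rr, m = 2L, r = NULL, k = 0.2) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < 10 * m)
    hrv_warn(sprintf("series length %d is below the 10*m guideline for m = %d",
                     n, m))
  r <- .resolve_r(x, r, k)
  if (r <= 0) {
    if (sd(x) == 0) return(0)  # constant series: all templates match at any r > 0
    hrv_stop("tolerance r must be positive for a non-constant series",
             class = "hrvrisk_config_error")
  }
  if (n < m + 2L)
    hrv_stop("series too short for embedding length ", m,
             class = "hrvrisk_validation_error")
  phi <- function(mm) {
    b <- .template_matches(x, mm, r)
    mean(log(rowMeans(b)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy of an RR series
#'
#' Richman-Moorman SmEn: `-log(A / B)` where `B` counts pairs of distinct
#' m-length templates within Chebyshev distance `r` and `A` the
#' corresponding (m+1)-length pairs, both over the first `n - m` template
#' positions and excluding self-comparison. When no matches exist at either
#' length the value is undefined and returned as `NA` with a warning (the
#' usual failure mode of large `m` on short 5-minute records).
#'
#' @inheritParams apen
#' @return Sample entropy (nats), or `NA` when undefined.
#' @export
smen <- function(rr, m = 2L, r = NULL, k = 0.2) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < 10 * m)
    hrv_warn(sprintf("series length %d is below the 10*m guideline for m = %d",
                     n, m))
  r <- .resolve_r(x, r, k)
  if (r <= 0) {
    if (sd(x) == 0) return(0)
    hrv_stop("tolerance r must be positive for a non-constant series",
             class = "hrvrisk_config_error")
  }
  if (n < m + 2L)
    hrv_stop("series too short for embedding length ", m,
             class = "hrvrisk_validation_error")
  nt <- n - m  # template positions used at both lengths
  bm <- .template_matches(x, m, r)[seq_len(nt), seq_len(nt), drop = FALSE]
  bm1 <- .template_matches(x, m + 1L, r)
  b_count <- sum(bm) - nt
  a_count <- sum(bm1) - nrow(bm1)
  if (a_count <= 0 || b_count <= 0) {
    hrv_warn(sprintf("sample entropy undefined at m = %d (no template matches)", m))
    return(NA_real_)
  }
  -log(a_count / b_count)
}

#' Complexity feature sweep
#'
#' ApEn and SmEn for embedding lengths `1..m_max` at tolerance
#' `r = k * sd(series)`, emitted as the named features
#' `ApEn_m1..ApEn_m{m_max}`, `SmEn_m1..SmEn_m{m_max}`.
#'
#' @inheritParams apen
#' @param m_max Largest embedding length (default 4).
#' @return Named numeric vector of `2 * m_max` features.
#' @export
complexity_features <- function(rr, m_max = 4L, k = 0.2) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  r <- k * sd(x)
  if (r <= 0 || n < m_max + 2L) {
    # constant (or too short) series: fall back to the scalar paths, which
    # handle the degenerate conventions
    out <- numeric(0)
    for (m in seq_len(m_max))
      out[paste0("ApEn_m", m)] <- suppressWarnings(apen(x, m = m, k = k))
    for (m in seq_len(m_max))
      out[paste0("SmEn_m", m)] <- suppressWarnings(smen(x, m = m, k = k))
    return(out)
  }
  # build the match matrices once by recurrence and read off both measures
  l1 <- abs(outer(x, x, `-`)) <= r
  bs <- vector("list", m_max + 1L)
  bs[[1L]] <- l1
  for (m in 2:(m_max + 1L)) {
    nm <- n - m + 1L
    bs[[m]] <- bs[[m - 1L]][seq_len(nm), seq_len(nm), drop = FALSE] &
      l1[m:n, m:n, drop = FALSE]
  }
  phi <- vapply(bs, function(b) mean(log(rowMeans(b))), numeric(1))
  out <- numeric(0)
  for (m in seq_len(m_max)) out[paste0("ApEn_m", m)] <- phi[m] - phi[m + 1L]
  for (m in seq_len(m_max)) {
    nt <- n - m
    bm <- bs[[m]][seq_len(nt), seq_len(nt), drop = FALSE]
    b_count <- sum(bm) - nt
    a_count <- sum(bs[[m + 1L]]) - nt
    out[paste0("SmEn_m", m)] <-
      if (a_count <= 0 || b_count <= 0) NA_real_ else -log(a_count / b_count)
  }
  out
}
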