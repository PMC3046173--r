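#' Detected R-peak set
#'
#' @param indices Strictly increasing sample indices of R peaks.
#' @param fs Sampling rate in Hz.
#' @param level Wavelet decomposition level used by the pre-filter.
#' @return An object of class `r_peak_set`. Peak pairs whose implied
#'   instantaneous heart rate falls outside 20--300 bpm are flagged in
#'   `hr_flags` (one flag per inter-peak interval) but not removed.
#' @export
r_peak_set <- function(indices, fs, level = NA_integer_) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    hrv_stop("R-peak indices must be strictly increasing",
             class = "hrvrisk_validation_error")
  hr <- if (length(indices) >= 2L) 60 * fs / diff(indices) else numeric(0)
  structure(list(indices = indices, fs = fs, level = level,
                 hr_flags = hr < 20 | hr > 300),
            class = "r_peak_set")
}

#' @export
print.r_peak_set <- function(x, ...) {
  cat(sprintf("<r_peak_set: %d peaks @ %g Hz (level %s)>\n",
              length(x$indices), x$fs, x$level))
  invisible(x)
}

# Pan-Tompkins stages on a (pre-filtered) ECG trace; returns candidate peak
# indices of the moving-window-integrated signal plus that signal
.pt_candidates <- function(y, fs) {
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  yb <- as.numeric(signal::filtfilt(bf, y))
  n <- length(yb)
  # centered five-point derivative
  der <- numeric(n)
  i <- 3:(n - 2)
  der[i] <- (2 * yb[i + 1] + yb[i + 2] - 2 * yb[i - 1] - yb[i - 2]) * fs / 8
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  zi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  zi[!is.finite(zi)] <- 0
  # local maxima with a 200 ms minimum separation (refractory period)
  cand <- which(diff(sign(diff(zi))) < 0) + 1L
  cand <- cand[zi[cand] > 0]
  if (length(cand) > 1L) {
    min_sep <- round(0.2 * fs)
    keep <- logical(length(cand))
    ord <- order(zi[cand], decreasing = TRUE)
    taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(cand[j] - taken) >= min_sep)) {
        keep[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- cand[keep]
    cand <- sort(cand)
  }
  list(cand = cand, zi = zi)
}

# adaptive dual-threshold beat classification with search-back
.pt_threshold <- function(cand, zi, fs) {
  if (!length(cand)) return(integer(0))
  init <- zi[seq_len(min(length(zi), 2L * round(fs)))]
  spk <- max(init)
  npk <- mean(init) / 2
  beats <- integer(0)
  rr_hist <- numeric(0)
  for (p in cand) {
    thr1 <- npk + 0.25 * (spk - npk)
    # search-back: long gap since the last beat -> revisit skipped
    # candidates against the halved threshold
    if (length(beats) && length(rr_hist) >= 2L) {
      rr_avg <- mean(tail(rr_hist, 8L))
      if ((p - tail(beats, 1L)) > 1.66 * rr_avg) {
        between <- cand[cand > tail(beats, 1L) & cand < p]
        between <- between[zi[between] > 0.5 * thr1]
        if (length(between)) {
          b <- between[which.max(zi[between])]
          spk <- 0.25 * zi[b] + 0.75 * spk
          rr_hist <- c(rr_hist, b - tail(beats, 1L))
          beats <- c(beats, b)
        }
      }
    }
    if (zi[p] > thr1 &&
        (!length(beats) || (p - tail(beats, 1L)) >= round(0.2 * fs))) {
      if (length(beats)) rr_hist <- c(rr_hist, p - tail(beats, 1L))
      spk <- 0.125 * zi[p] + 0.875 * spk
      beats <- c(beats, p)
    } else {
      npk <- 0.125 * zi[p] + 0.875 * npk
    }
  }
  beats
}

#' Detect R peaks in an ECG record
#'
#' The detector reconstructs the ECG from its Haar wavelet detail
#' coefficients at levels 1..`level` (discarding the lowpass branch, which
#' carries baseline wander), runs the Pan-Tompkins algorithm on the
#' reconstruction (5--15 Hz band-pass, derivative, squaring, 150 ms
#' moving-window integration, adaptive dual threshold with a 200 ms
#' refractory period and search-back), and finally refines each fiducial to
#' the local extremum of the raw trace within +/-50 ms.
#'
#' @param ecg An [ecg_record].
#' @param level Haar decomposition level for the detail pre-filter (1--4).
#' @param wavelet Mother wavelet of the pre-filter.
#' @return An [r_peak_set].
#' @export
detect_r_peaks <- function(ecg, level = 4L, wavelet = "haar") {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!level %in% 1:4)
    hrv_stop("'level' must be in 1..4", class = "hrvrisk_config_error")
  if (ecg$fs < 40)
    hrv_stop("sampling rate too low for the 5-15 Hz band-pass (fs < 40 Hz)",
             class = "hrvrisk_config_error")
  y <- wt_detail_reconstruct(ecg$samples, level, wavelet)
  pt <- .pt_candidates(y, ecg$fs)
  beats <- .pt_threshold(pt$cand, pt$zi, ecg$fs)
  if (!length(beats))
    return(r_peak_set(integer(0), ecg$fs, level))
  # refine to the raw-signal extremum within +/-50 ms
  half <- as.integer(round(0.05 * ecg$fs))
  base <- median(ecg$samples)
  n <- length(ecg$samples)
  refined <- vapply(beats, function(b) {
    lo <- max(1L, as.integer(b) - half)
    hi <- min(n, as.integer(b) + half)
    lo + which.max(abs(ecg$samples[lo:hi] - base)) - 1L
  }, integer(1))
  r_peak_set(sort(unique(refined)), ecg$fs, level)
}

#' Score R-peak detection against ground truth
#'
#' Greedy one-to-one matching of detected against true peak positions
#' within a tolerance window. Sensitivity is `100*TP/(TP+FN)` and accuracy
#' `100*TP/(TP+FN+FP)`.
#'
#' @param detected An [r_peak_set] or integer sample indices.
#' @param truth True R-peak sample indices (ascending).
#' @param tol_ms Matching window in ms (default 50).
#' @param fs Sampling rate, required when `detected` is a bare index vector.
#' @return A list of class `detection_score` with `FP`, `FN`, `TP`, `Se`,
#'   `Ac`.
#' @export
score_detection <- function(detected, truth, tol_ms = 50, fs = NULL) {
  if (inherits(detected, "r_peak_set")) {
    fs <- detected$fs
    detected <- detected$indices
  }
  if (is.null(fs))
    hrv_stop("'fs' is required when 'detected' is not an r_peak_set",
             class = "hrvrisk_config_error")
  stopifnot_scalar_num(tol_ms, "tol_ms", lower = 0, strict_lower = TRUE)
  truth <- sort(as.numeric(truth))
  detected <- sort(as.numeric(detected))
  tol <- tol_ms / 1000 * fs
  tp <- 0L
  i <- 1L
  j <- 1L
  while (i <= length(detected) && j <= length(truth)) {
    if (abs(detected[i] - truth[j]) <= tol) {
      tp <- tp + 1L
      i <- i + 1L
      j <- j + 1L
    } else if (detected[i] < truth[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ac <- if (tp + fn + fp > 0) 100 * tp / (tp + fn + fp) else NA_real_
  structure(list(TP = tp, FP = fp, FN = fn, Se = se, Ac = ac),
            class = "detection_score")
}

#' Build the RR series from detected peaks
#'
#' @param peaks An [r_peak_set] with at least two peaks.
#' @return An [rr_series] of `length(peaks) - 1` intervals in ms.
#' @export
rr_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "r_peak_set"))
  if (length(peaks$indices) < 2L)
    hrv_stop("need at least 2 peaks to form intervals",
             class = "hrvrisk_empty_error")
  rr_series(1000 * diff(peaks$indices) / peaks$fs, id = "rr_from_peaks")
}

# Rosner (generalized ESD) critical value for step i of k on sample size n
.rosner_lambda <- function(n, i, alpha) {
  ni <- n - i + 1
  tcrit <- qt(1 - alpha / (2 * ni), df = ni - 2)
  (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
}

#' Remove ectopic intervals with the generalized ESD (Rosner) test
#'
#' Iteratively removes the most extreme interval (largest
#' `|x - mean| / sd`, sample sd) up to `k_max` times, comparing each test
#' statistic against Rosner's t-distribution critical value at level
#' `alpha`. The number of outliers declared is the largest step whose
#' statistic exceeds its critical value; declared outliers are dropped from
#' the series with order otherwise preserved. Removal is preferred over
#' interpolation for ectopic beats.
#'
#' @param rr An [rr_series] of length >= 10.
#' @param k_max Outlier budget; default `ceiling(0.05 * length)`.
#' @param alpha Significance level in (0, 1).
#' @return A list with `rr` (cleaned [rr_series]) and `report` (class
#'   `outlier_report`: `removed_indices` into the input series,
#'   per-iteration `statistics` and `lambdas`, `alpha`, `k_max`).
#' @export
rosner_filter <- function(rr, k_max = NULL, alpha = 0.05) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  n <- length(x)
  if (n < 10L)
    hrv_stop("need at least 10 intervals for the outlier test",
             class = "hrvrisk_validation_error")
  stopifnot_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (alpha >= 1)
    hrv_stop("'alpha' must be in (0, 1)", class = "hrvrisk_config_error")
  k_max <- k_max %||% ceiling(0.05 * n)
  if (k_max < 0 || k_max != round(k_max))
    hrv_stop("'k_max' must be a non-negative integer",
             class = "hrvrisk_config_error")
  if (k_max >= n / 2)
    hrv_stop("'k_max' >= length/2 makes the test degenerate",
             class = "hrvrisk_config_error")
  stats_r <- numeric(0)
  lambdas <- numeric(0)
  cand <- integer(0)
  cur <- seq_len(n)
  for (i in seq_len(k_max)) {
    xs <- x[cur]
    s <- sd(xs)
    if (!is.finite(s) || s == 0) break  # degenerate dispersion: stop testing
    dev <- abs(xs - mean(xs)) / s
    j <- which.max(dev)
    stats_r <- c(stats_r, dev[j])
    lambdas <- c(lambdas, .rosner_lambda(n, i, alpha))
    cand <- c(cand, cur[j])
    cur <- cur[-j]
  }
  exceeds <- which(stats_r > lambdas)
  n_out <- if (length(exceeds)) max(exceeds) else 0L
  removed <- if (n_out > 0L) cand[seq_len(n_out)] else integer(0)
  cleaned <- if (length(removed)) x[-removed] else x
  report <- structure(list(removed_indices = removed, statistics = stats_r,
                           lambdas = lambdas, alpha = alpha, k_max = k_max),
                      class = "outlier_report")
  list(rr = rr_series(cleaned, id = rr$id), report = report)
}
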