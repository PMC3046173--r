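#' Extract all four HRV feature families from an NN series
#'
#' Runs the time-domain, spectral (4 Hz cubic resampling, smoothness-priors
#' detrending, AR(16) band powers), wavelet-packet (DB4, level 5) and
#' nonlinear (Poincare, ApEn/SmEn sweep) extractors on one cleaned NN
#' series and returns a single named feature vector.
#'
#' @param rr An [rr_series] (>= 64 intervals for the wavelet features).
#' @param fs_i Tachogram interpolation rate in Hz.
#' @param ar_order AR model order for the spectral estimate.
#' @param lambda Smoothness-priors detrending parameter.
#' @param wavelet,wp_level Wavelet-packet mother wavelet and depth.
#' @param bin_ms Poincare histogram bin width in ms.
#' @param k Entropy tolerance factor (`r = k * sd`).
#' @param m_max Largest entropy embedding length.
#' @return Named numeric vector with 7 statistical, 6 spectral,
#'   `2 * (2^(wp_level+1) - 2)` wavelet and `5 + 2 * m_max` nonlinear
#'   features.
#' @export
extract_features <- function(rr, fs_i = 4, ar_order = 16L, lambda = 500,
                             wavelet = "db4", wp_level = 5L,
                             bin_ms = 7.8125, k = 0.2, m_max = 4L) {
  stopifnot(inherits(rr, "rr_series"))
  tach <- detrend_sp(resample_rr(rr, fs_i = fs_i), lam = lambda)
  spec <- suppressWarnings(
    band_powers(ar_psd(tach, p = ar_order, id = rr$id)))
  c(time_domain_features(rr),
    spec,
    wp_features(rr, wavelet = wavelet, level = wp_level)$features,
    poincare_features(rr, bin_ms = bin_ms),
    complexity_features(rr, m_max = m_max, k = k))
}

#' Extract features for a labeled cohort
#'
#' @param cohort An `rr_cohort` (see [generate_cohort]) or a list with
#'   `series` (named list of [rr_series]) and `labels` (named character
#'   vector, `"N"`/`"R"`).
#' @param clean Apply [rosner_filter] to each series first (default TRUE).
#' @param alpha,k_max Outlier-test parameters passed to [rosner_filter].
#' @param ... Passed to [extract_features].
#' @return Data frame with `id`, `class` and one column per feature.
#' @export
cohort_features <- function(cohort, clean = TRUE, alpha = 0.05,
                            k_max = NULL, ...) {
  stopifnot(is.list(cohort), !is.null(cohort$series), !is.null(cohort$labels))
  ids <- names(cohort$series)
  rows <- lapply(ids, function(id) {
    rr <- cohort$series[[id]]
    if (clean) rr <- rosner_filter(rr, k_max = k_max, alpha = alpha)$rr
    extract_features(rr, ...)
  })
  sets <- unique(lapply(rows, names))
  if (length(sets) > 1L)
    hrv_stop("records produced inconsistent feature sets",
             class = "hrvrisk_schema_error")
  feat <- do.call(rbind, rows)
  data.frame(id = ids, class = unname(cohort$labels[ids]), feat,
             check.names = FALSE, row.names = NULL)
}
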