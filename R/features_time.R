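#' Time-domain (statistical) HRV indexes
#'
#' Computes the seven classical short-term statistical indexes of an NN
#' series:
#' \describe{
#'   \item{meanNN}{mean interval (ms)}
#'   \item{SDNN}{sample standard deviation of the intervals (ms)}
#'   \item{RMSSD}{root mean square of successive differences (ms)}
#'   \item{pNN50}{fraction of successive differences strictly greater than
#'     50 ms (the denominator is the number of successive differences,
#'     the Task-Force convention)}
#'   \item{MIRR}{interquartile range Q3 - Q1 of the intervals (ms),
#'     quartiles by linear interpolation of the empirical CDF}
#'   \item{MDARR}{median absolute successive difference (ms)}
#'   \item{SDSD}{sample standard deviation of the successive differences
#'     (ms)}
#' }
#'
#' @param rr An [rr_series] with at least 3 intervals.
#' @return Named numeric vector with the seven indexes.
#' @export
time_domain_features <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 3L)
    hrv_stop("need at least 3 intervals for time-domain features",
             class = "hrvrisk_validation_error")
  d <- diff(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(meanNN = mean(x),
    SDNN = sd(x),
    RMSSD = sqrt(mean(d^2)),
    pNN50 = sum(abs(d) > 50) / length(d),
    MIRR = q[2L] - q[1L],
    MDARR = median(abs(d)),
    SDSD = sd(d))
}
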