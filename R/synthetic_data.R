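#' Specification of a synthetic two-class HRV cohort
#'
#' Describes the study conditions the generator emulates: 5-minute NN
#' series with a low-frequency (Mayer-wave, 0.1 Hz) and a high-frequency
#' (respiratory sinus arrhythmia, 0.2 Hz = 12 breaths/min) oscillation plus
#' beat-to-beat noise, and a cardiovascular-risk class whose oscillation
#' amplitudes and noise are shrunk by `risk_scaling` (the
#' reduced-variability phenotype). `risk_mode = "excessive"` instead
#' amplifies the risk-class noise and injects occasional ectopic-like
#' spikes, the alternative risk signature.
#'
#' @param n_per_class Records per class (default 45).
#' @param duration_s Record length in seconds (default 300).
#' @param base_rr_ms Mean NN interval in ms (default 850).
#' @param lf_amp_ms,hf_amp_ms Oscillation amplitudes in ms.
#' @param lf_hz,hf_hz Oscillation frequencies in Hz.
#' @param noise_sd_ms Beat-to-beat Gaussian noise sd in ms.
#' @param risk_scaling Multiplier in (0, 1] applied to the risk-class
#'   amplitudes and noise (default 0.5).
#' @param risk_base_shift_ms Additive shift of the risk-class mean interval
#'   (default 0).
#' @param risk_mode `"reduced"` (default) or `"excessive"`.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 45L, duration_s = 300,
                        base_rr_ms = 850, lf_amp_ms = 30, hf_amp_ms = 20,
                        lf_hz = 0.1, hf_hz = 0.2, noise_sd_ms = 12,
                        risk_scaling = 0.5, risk_base_shift_ms = 0,
                        risk_mode = c("reduced", "excessive"), seed = 1L) {
  risk_mode <- match.arg(risk_mode)
  stopifnot_scalar_num(n_per_class, "n_per_class", lower = 1)
  stopifnot_scalar_num(duration_s, "duration_s", lower = 0,
                       strict_lower = TRUE)
  stopifnot_scalar_num(base_rr_ms, "base_rr_ms", lower = 0,
                       strict_lower = TRUE)
  for (nm in c("lf_amp_ms", "hf_amp_ms", "noise_sd_ms"))
    stopifnot_scalar_num(get(nm), nm, lower = 0)
  for (nm in c("lf_hz", "hf_hz")) {
    v <- get(nm)
    if (v <= 0 || v >= 0.5)
      hrv_stop("'", nm, "' must lie in (0, 0.5) Hz",
               class = "hrvrisk_config_error")
  }
  if (risk_scaling <= 0 || risk_scaling > 1)
    hrv_stop("'risk_scaling' must lie in (0, 1]",
             class = "hrvrisk_config_error")
  structure(list(n_per_class = as.integer(n_per_class),
                 duration_s = duration_s, base_rr_ms = base_rr_ms,
                 lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
                 lf_hz = lf_hz, hf_hz = hf_hz, noise_sd_ms = noise_sd_ms,
                 risk_scaling = risk_scaling,
                 risk_base_shift_ms = risk_base_shift_ms,
                 risk_mode = risk_mode, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one synthetic NN series
#'
#' `RR_n = base + lf_amp sin(2 pi lf_hz t_n + phase_1) + hf_amp sin(2 pi
#' hf_hz t_n + phase_2) + N(0, noise_sd)`, with `t_n` the cumulative beat
#' time (an implicit point-process sampling of the modulation), random
#' phases, and all intervals clipped to the physiological range
#' 300--2000 ms. Deterministic for a fixed seed.
#'
#' @param base_rr_ms Mean interval (ms).
#' @param lf_amp_ms,hf_amp_ms,lf_hz,hf_hz Oscillation parameters.
#' @param noise_sd_ms Gaussian noise sd (ms).
#' @param duration_s Target record length (s).
#' @param spike_rate Probability per beat of an ectopic-like spike
#'   (interval halved or doubled); 0 by default.
#' @param seed Integer seed.
#' @param id Record label.
#' @return An [rr_series].
#' @export
generate_rr <- function(base_rr_ms = 850, lf_amp_ms = 30, hf_amp_ms = 20,
                        lf_hz = 0.1, hf_hz = 0.2, noise_sd_ms = 12,
                        duration_s = 300, spike_rate = 0, seed = 1L,
                        id = "synthetic") {
  if (base_rr_ms - lf_amp_ms - hf_amp_ms <= 0)
    hrv_stop("oscillation amplitudes imply non-positive intervals",
             class = "hrvrisk_config_error")
  set.seed(seed)
  phase <- runif(2, 0, 2 * pi)
  t_now <- 0
  out <- numeric(0)
  while (t_now < duration_s) {
    rr <- base_rr_ms +
      lf_amp_ms * sin(2 * pi * lf_hz * t_now + phase[1L]) +
      hf_amp_ms * sin(2 * pi * hf_hz * t_now + phase[2L]) +
      rnorm(1, 0, noise_sd_ms)
    if (spike_rate > 0 && runif(1) < spike_rate)
      rr <- rr * sample(c(0.5, 2), 1L)
    rr <- min(2000, max(300, rr))
    out <- c(out, rr)
    t_now <- t_now + rr / 1000
  }
  rr_series(out, id = id)
}

# PQRST template: amplitude (mV), offset from the R apex (s), width (s)
.pqrst_waves <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  amp = c(0.10, -0.15, 1.00, -0.25, 0.35),
  mu = c(-0.200, -0.025, 0.000, 0.025, 0.220),
  sigma = c(0.045, 0.010, 0.011, 0.012, 0.060))

#' Generate a synthetic ECG from an NN series
#'
#' Places a PQRST template (a sum of Gaussian bumps) at the cumulative
#' beat times of `rr`, snapped to the sample grid so the returned truth
#' indices are exactly the template R apices. Optional additive Gaussian
#' noise and a 0.3 Hz sinusoidal baseline wander. A matching sinusoidal
#' respiration channel at `resp_hz` can be attached for the breathing-rate
#' check.
#'
#' @param rr An [rr_series].
#' @param fs Sampling rate in Hz (>= 100).
#' @param noise_sd Additive noise sd in mV.
#' @param baseline_amp Baseline-wander amplitude in mV (0 disables).
#' @param resp_hz Respiration frequency for the optional respiration
#'   channel; `NULL` omits the channel.
#' @param seed Integer seed.
#' @return List with `ecg` (an [ecg_record]) and `truth` (R-apex sample
#'   indices).
#' @export
generate_ecg <- function(rr, fs = 250, noise_sd = 0, baseline_amp = 0,
                         resp_hz = NULL, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100)
    hrv_stop("'fs' must be at least 100 Hz", class = "hrvrisk_config_error")
  set.seed(seed)
  beat_t <- 0.5 + c(0, cumsum(rr$intervals)) / 1000
  beat_t <- round(beat_t * fs) / fs          # snap apices to the grid
  truth <- as.integer(round(beat_t * fs)) + 1L
  n <- as.integer(ceiling((beat_t[length(beat_t)] + 0.6) * fs))
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (w in seq_len(nrow(.pqrst_waves))) {
    amp <- .pqrst_waves$amp[w]
    mu <- .pqrst_waves$mu[w]
    sg <- .pqrst_waves$sigma[w]
    for (bt in beat_t) {
      lo <- max(1L, as.integer(floor((bt + mu - 4 * sg) * fs)))
      hi <- min(n, as.integer(ceiling((bt + mu + 4 * sg) * fs)))
      if (hi >= lo) {
        seg <- lo:hi
        x[seg] <- x[seg] + amp * exp(-((tt[seg] - bt - mu)^2) / (2 * sg^2))
      }
    }
  }
  if (baseline_amp > 0) x <- x + baseline_amp * sin(2 * pi * 0.3 * tt)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  resp <- if (!is.null(resp_hz)) sin(2 * pi * resp_hz * tt) else NULL
  list(ecg = ecg_record(x, fs = fs, id = rr$id, respiration = resp),
       truth = truth)
}

#' Generate a labeled two-class cohort of NN series
#'
#' `n_per_class` normal records plus `n_per_class` risk records. Under the
#' default reduced-variability mode the risk class scales the LF/HF
#' amplitudes and the noise sd by `risk_scaling`; under the excessive mode
#' it divides the noise by `risk_scaling` and adds ectopic-like spikes.
#' Per-record seeds are `seed + record index`, so the whole cohort is
#' reproducible bit for bit.
#'
#' @param spec A [cohort_spec].
#' @return Object of class `rr_cohort`: named list `series` of
#'   [rr_series] (ids `N001..`, `R001..`) and named character vector
#'   `labels` (`"N"`/`"R"`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  series <- list()
  labels <- character(0)
  idx <- 0L
  for (cls in c("N", "R")) {
    risk <- cls == "R"
    scale_amp <- if (risk && spec$risk_mode == "reduced") spec$risk_scaling
                 else 1
    noise <- if (!risk) spec$noise_sd_ms
             else if (spec$risk_mode == "reduced")
               spec$noise_sd_ms * spec$risk_scaling
             else spec$noise_sd_ms / spec$risk_scaling
    spikes <- if (risk && spec$risk_mode == "excessive") 0.02 else 0
    base <- spec$base_rr_ms + if (risk) spec$risk_base_shift_ms else 0
    for (i in seq_len(spec$n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s%03d", cls, i)
      series[[id]] <- generate_rr(
        base_rr_ms = base,
        lf_amp_ms = spec$lf_amp_ms * scale_amp,
        hf_amp_ms = spec$hf_amp_ms * scale_amp,
        lf_hz = spec$lf_hz, hf_hz = spec$hf_hz,
        noise_sd_ms = noise, duration_s = spec$duration_s,
        spike_rate = spikes, seed = spec$seed + idx, id = id)
      labels[id] <- cls
    }
  }
  structure(list(series = series, labels = labels, spec = spec),
            class = "rr_cohort")
}

#' @export
print.rr_cohort <- function(x, ...) {
  cat(sprintf("<rr_cohort: %d records (%s)>\n", length(x$series),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk as RR files plus a labels manifest
#'
#' @param cohort An `rr_cohort`.
#' @param dir Output directory (created if needed); one `<id>.txt` RR file
#'   per record and a `labels.csv` manifest (`id`, `class`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$series))
    write_rr(cohort$series[[id]], file.path(dir, paste0(id, ".txt")))
  write.csv(data.frame(id = names(cohort$labels),
                       class = unname(cohort$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
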