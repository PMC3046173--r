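#' Breathing-rate validity check
#'
#' HRV comparisons between records are only meaningful when the breathing
#' rate is steady and close to the 12 breaths/min protocol rate, because
#' respiratory sinus arrhythmia moves with it. The rate is the dominant
#' spectral frequency of the respiration channel within 0.05--0.7 Hz
#' (times 60); validity additionally requires the windowed rate (60 s
#' windows) to vary by at most `sd_tol`.
#'
#' @param respiration Numeric respiration signal (>= 60 s), or `NULL`.
#' @param fs Sampling rate in Hz.
#' @param target Protocol breathing rate (breaths/min, default 12).
#' @param tol Allowed deviation from `target` (default 3 breaths/min).
#' @param sd_tol Allowed sd of the windowed rate (default 2 breaths/min).
#' @return List with `status` (`"checked"`/`"unchecked"`), `rate`
#'   (breaths/min), `window_sd` and `valid`. A missing channel yields
#'   `status = "unchecked"` rather than an error; invalid records are
#'   flagged as advisory-only downstream, never dropped.
#' @export
breathing_check <- function(respiration, fs, target = 12, tol = 3,
                            sd_tol = 2) {
  if (is.null(respiration))
    return(list(status = "unchecked", rate = NA_real_,
                window_sd = NA_real_, valid = NA))
  x <- as.numeric(respiration)
  if (length(x) < 60 * fs)
    hrv_stop("need at least 60 s of respiration signal",
             class = "hrvrisk_validation_error")
  dominant <- function(seg) {
    seg <- seg - mean(seg)
    n <- length(seg)
    sp <- Mod(fft(seg))^2
    fr <- (seq_len(n) - 1L) * fs / n
    band <- fr >= 0.05 & fr <= 0.7
    fr[band][which.max(sp[band])]
  }
  rate <- 60 * dominant(x)
  w <- as.integer(60 * fs)
  n_win <- floor(length(x) / w)
  win_rates <- vapply(seq_len(n_win), function(i) {
    60 * dominant(x[((i - 1L) * w + 1L):(i * w)])
  }, numeric(1))
  window_sd <- if (n_win > 1L) sd(win_rates) else 0
  list(status = "checked", rate = rate, window_sd = window_sd,
       valid = abs(rate - target) <= tol && window_sd <= sd_tol)
}

# fill missing config entries with defaults, recursively
.merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && is.list(cfg[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], cfg[[nm]])
    else defaults[[nm]] <- cfg[[nm]]
  }
  defaults
}

.pipeline_defaults <- function() {
  list(
    input = list(rr_dir = NULL, ecg_dir = NULL, fs = 250, labels = NULL,
                 synthetic = NULL),
    preprocessing = list(level = 4, alpha = 0.05, k_max = NULL),
    features = list(fs_i = 4, ar_order = 16, lambda = 500,
                    wavelet = "db4", wp_level = 5, bin_ms = 7.8125,
                    k = 0.2, m_max = 4),
    selection = list(alpha_select = 0.01, alpha_significant = 0.05,
                     top_k = 5),
    classifier = list(scheme = "mlp", repeats = 1, hidden = 200,
                      centers = 3, alpha_select = 1),
    seed = 1L,
    output_dir = NULL)
}

# load a labeled RR cohort per the input config
.load_cohort <- function(input, level) {
  if (!is.null(input$synthetic)) {
    sp <- do.call(cohort_spec, input$synthetic)
    return(generate_cohort(sp))
  }
  if (is.null(input$rr_dir) && is.null(input$ecg_dir) ||
      is.null(input$labels))
    hrv_stop("config must name rr_dir, ecg_dir or synthetic input (with labels)",
             class = "hrvrisk_config_error")
  labels_df <- read.csv(input$labels)
  labels <- stats::setNames(as.character(labels_df$class),
                            as.character(labels_df$id))
  series <- list()
  if (!is.null(input$rr_dir)) {
    for (id in names(labels))
      series[[id]] <- read_rr(file.path(input$rr_dir, paste0(id, ".txt")),
                              id = id)
  } else if (!is.null(input$ecg_dir)) {
    for (id in names(labels)) {
      ecg <- suppressWarnings(
        read_ecg(file.path(input$ecg_dir, paste0(id, ".txt")),
                 fs = input$fs, id = id))
      series[[id]] <- rr_from_peaks(detect_r_peaks(ecg, level = level))
    }
  } else {
    hrv_stop("config must name rr_dir, ecg_dir or synthetic input",
             class = "hrvrisk_config_error")
  }
  structure(list(series = series, labels = labels), class = "rr_cohort")
}

#' Run the full prognosis pipeline
#'
#' Orchestrates the end-to-end flow: load (or synthesize) the cohort,
#' remove ectopic intervals, extract all four feature families, screen
#' features with the two-sample KS test, and run the classifier protocol
#' (stratified 2/3--1/3 split(s), training-split MinMax normalization and
#' top-k selection). Every stage records its parameters in the returned
#' provenance log; reports are written as CSV/JSON when `output_dir` is
#' set and contain no timestamps, so identical configurations reproduce
#' byte-identical artifacts.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   nested list. Recognized blocks (all optional except `input`):
#'   `input` (`rr_dir` + `labels`, or `ecg_dir` + `fs` + `labels`, or
#'   `synthetic` = [cohort_spec] arguments), `preprocessing` (`level`,
#'   `alpha`, `k_max`), `features` (see [extract_features]), `selection`
#'   (`alpha_select`, `top_k`), `classifier` (`scheme`, `repeats`,
#'   `hidden`, `centers`), `seed`, `output_dir`.
#' @return Object of class `hrv_prognosis`: `features` (table),
#'   `selection` (cohort-level [select_features] report), `cv`
#'   ([cross_validate] result), `breathing` (per-record check status when
#'   respiration was available) and `log` (stage provenance).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.pipeline_defaults(), config)
  # validate up front, before any computation
  schemes <- c("mlp", "rbf", "svm-linear", "svm-poly", "svm-rbf")
  if (!cfg$classifier$scheme %in% schemes)
    hrv_stop("unknown classifier scheme '", cfg$classifier$scheme, "'",
             class = "hrvrisk_config_error")
  log <- list(config = cfg)
  cohort <- .load_cohort(cfg$input, cfg$preprocessing$level)
  log$records <- length(cohort$series)
  ftab <- cohort_features(
    cohort, clean = TRUE, alpha = cfg$preprocessing$alpha,
    k_max = cfg$preprocessing$k_max,
    fs_i = cfg$features$fs_i, ar_order = cfg$features$ar_order,
    lambda = cfg$features$lambda, wavelet = cfg$features$wavelet,
    wp_level = cfg$features$wp_level, bin_ms = cfg$features$bin_ms,
    k = cfg$features$k, m_max = cfg$features$m_max)
  log$n_features <- ncol(ftab) - 2L
  sel <- suppressWarnings(select_features(
    ftab, alpha_select = cfg$selection$alpha_select,
    alpha_significant = cfg$selection$alpha_significant,
    top_k = cfg$selection$top_k))
  cv <- cross_validate(
    ftab, scheme = cfg$classifier$scheme, top_k = cfg$selection$top_k,
    seed = cfg$seed, repeats = cfg$classifier$repeats,
    alpha_select = cfg$classifier$alpha_select,
    hidden = cfg$classifier$hidden, centers = cfg$classifier$centers)
  out <- structure(list(features = ftab, selection = sel, cv = cv,
                        log = log),
                   class = "hrv_prognosis")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(ftab, file.path(cfg$output_dir, "features.csv"))
    jsonlite::write_json(
      list(alpha_select = sel$alpha_select, selected = sel$selected,
           stats = sel$stats),
      file.path(cfg$output_dir, "selection.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(
      list(scheme = cv$scheme,
           summary = cv$summary,
           selected = cv$selected,
           reports = lapply(cv$reports, function(r)
             list(confusion = as.list(r$confusion),
                  metrics = as.list(r$metrics), auc = r$auc))),
      file.path(cfg$output_dir, "classifier.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}

#' @export
print.hrv_prognosis <- function(x, ...) {
  cat(sprintf("<hrv_prognosis: %d records, %d features>\n",
              nrow(x$features), x$log$n_features))
  print(x$selection)
  print(x$cv)
  invisible(x)
}
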