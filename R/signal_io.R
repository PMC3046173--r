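#' ECG record container
#'
#' Holds a sampled single-lead ECG voltage trace together with its sampling
#' rate, an identifier, and an optional simultaneously sampled respiration
#' channel (used only for the breathing-rate validity check).
#'
#' @param samples Numeric vector of voltages (arbitrary units, typically mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param id Record label.
#' @param respiration Optional numeric vector, same length as `samples`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, id = "ecg", respiration = NULL) {
  stopifnot_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    hrv_stop("ECG samples contain non-finite values",
             class = "hrvrisk_validation_error")
  if (length(samples) < 2 * fs)
    hrv_stop("ECG record '", id, "' is shorter than 2 s",
             class = "hrvrisk_validation_error")
  if (!is.null(respiration)) {
    respiration <- as.numeric(respiration)
    if (length(respiration) != length(samples))
      hrv_stop("respiration channel length must match the ECG samples",
               class = "hrvrisk_validation_error")
  }
  structure(list(samples = samples, fs = fs, id = as.character(id),
                 respiration = respiration),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.1f s)%s>\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$respiration)) "" else ", respiration channel"))
  invisible(x)
}

#' NN/RR interval series container
#'
#' An ordered series of normal-to-normal (NN) heartbeat intervals in
#' milliseconds. All intervals must be finite and strictly positive.
#'
#' @param intervals Numeric vector of intervals in ms.
#' @param id Record label.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, id = "rr") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L)
    hrv_stop("empty interval series", class = "hrvrisk_empty_error")
  if (any(!is.finite(intervals)))
    hrv_stop("RR intervals contain non-finite values",
             class = "hrvrisk_validation_error")
  bad <- which(intervals <= 0)
  if (length(bad))
    hrv_stop("non-positive RR intervals at indices: ",
             paste(head(bad, 10L), collapse = ", "),
             class = "hrvrisk_validation_error")
  structure(list(intervals = intervals, id = as.character(id)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series '%s': %d intervals, mean %.1f ms>\n",
              x$id, length(x$intervals), mean(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

# split delimited text lines into numeric fields (comma / tab / whitespace)
.split_fields <- function(lines) {
  strsplit(trimws(lines), "[,;\t ]+")
}

#' Read a delimited ECG signal file
#'
#' Accepts one numeric column (voltage only) or two (time in seconds,
#' voltage). The delimiter is auto-detected among comma, semicolon, tab and
#' whitespace; `#` comment lines and blank lines are skipped. When a time
#' column is present the sampling rate implied by the median time step must
#' agree with `fs` within 1%, otherwise the supplied `fs` wins with a
#' warning.
#'
#' @param path Path to the signal file.
#' @param fs Sampling rate in Hz.
#' @param id Record label (defaults to the file name).
#' @return An [ecg_record].
#' @export
read_ecg <- function(path, fs, id = NULL) {
  if (!file.exists(path))
    hrv_stop("file not found: ", path, class = "hrvrisk_io_error")
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    hrv_stop("empty ECG file: ", path, class = "hrvrisk_empty_error")
  fields <- .split_fields(lines[keep])
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]) || !(ncols[1L] %in% c(1L, 2L)))
    hrv_stop("expected 1 or 2 numeric columns throughout: ", path,
             class = "hrvrisk_parse_error")
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncols[1L], byrow = TRUE))
  bad <- which(rowSums(!is.finite(mat)) > 0)
  if (length(bad)) {
    line_no <- which(keep)[bad[1L]]
    hrv_stop("non-numeric or non-finite value at line ", line_no, " of ",
             path, class = "hrvrisk_parse_error")
  }
  if (ncols[1L] == 2L) {
    dt <- median(diff(mat[, 1L]))
    if (is.finite(dt) && dt > 0) {
      fs_inferred <- 1 / dt
      if (abs(fs_inferred - fs) / fs > 0.01)
        hrv_warn(sprintf(
          "time column implies fs = %.4g Hz but fs = %.4g Hz was given; using the given value",
          fs_inferred, fs))
    }
    volt <- mat[, 2L]
  } else {
    volt <- mat[, 1L]
  }
  if (length(volt) < 300 * fs)
    hrv_warn(sprintf("record '%s' is shorter than the 5-minute protocol length (%.1f s)",
                     id, length(volt) / fs))
  ecg_record(volt, fs = fs, id = id)
}

#' Read an RR interval file
#'
#' One interval per line, in milliseconds; `#` comment lines and blank lines
#' are skipped.
#'
#' @param path Path to the RR file.
#' @param id Record label (defaults to the file name).
#' @return An [rr_series].
#' @export
read_rr <- function(path, id = NULL) {
  if (!file.exists(path))
    hrv_stop("file not found: ", path, class = "hrvrisk_io_error")
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep))
    hrv_stop("empty RR file: ", path, class = "hrvrisk_empty_error")
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (any(is.na(vals))) {
    line_no <- which(keep)[which(is.na(vals))[1L]]
    hrv_stop("non-numeric value at line ", line_no, " of ", path,
             class = "hrvrisk_parse_error")
  }
  rr_series(vals, id = id)
}

#' Write an RR interval series
#'
#' One interval per line with three decimals, so that
#' `read_rr(write_rr(x))` round-trips exactly at ms precision.
#'
#' @param rr An [rr_series].
#' @param path Output path.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(sprintf("%.3f", rr$intervals), path)
  invisible(path)
}

# family of a feature name; order of levels fixes the column order of
# write_features: statistical, spectral, wavelet, nonlinear
feature_family <- function(names) {
  fam <- rep("other", length(names))
  fam[names %in% c("meanNN", "SDNN", "RMSSD", "pNN50", "MIRR", "MDARR",
                   "SDSD")] <- "statistical"
  fam[names %in% c("VLF", "LF", "HF", "NLF", "NHF", "LFHF")] <- "spectral"
  fam[grepl("^wp[ES]_", names)] <- "wavelet"
  fam[names %in% c("SD1", "SD2", "widthNN", "widthW", "widthL") |
        grepl("^(ApEn|SmEn)_m[0-9]+$", names)] <- "nonlinear"
  factor(fam, levels = c("statistical", "spectral", "wavelet", "nonlinear",
                         "other"))
}

# deterministic column order: family blocks, alphabetical inside each family
order_feature_names <- function(names) {
  fam <- feature_family(names)
  names[order(as.integer(fam), match(names, sort_c(names)))]
}

#' Write a feature table
#'
#' Writes one row per record as CSV with a header of feature names. Columns
#' are ordered deterministically: statistical, spectral, wavelet, then
#' nonlinear features, alphabetically within each family.
#'
#' @param features A data frame with an `id` column (and optionally a
#'   `class` column) plus numeric feature columns, or a named list of named
#'   numeric vectors sharing one feature-name set.
#' @param path Output path.
#' @return The written data frame, invisibly.
#' @export
write_features <- function(features, path) {
  if (is.list(features) && !is.data.frame(features)) {
    if (length(features)) {
      sets <- lapply(features, function(v) sort_c(names(v)))
      if (length(unique(sets)) > 1L)
        hrv_stop("records carry inconsistent feature-name sets",
                 class = "hrvrisk_schema_error")
      features <- data.frame(
        id = names(features) %||% as.character(seq_along(features)),
        do.call(rbind, lapply(features, function(v) v[sets[[1L]]])),
        check.names = FALSE, row.names = NULL)
    } else {
      features <- data.frame(id = character(0))
    }
  }
  meta <- intersect(c("id", "class"), names(features))
  feat <- setdiff(names(features), meta)
  out <- features[, c(meta, order_feature_names(feat)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
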