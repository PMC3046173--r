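# internal helpers shared across modules

hrv_stop <- function(..., class = "hrvrisk_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

hrv_warn <- function(...) warning(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divisor n); the sample convention is stats::sd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# trapezoidal integral of y over x (x ascending)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# locale-independent alphabetical sort
sort_c <- function(x) sort(x, method = "radix")

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    hrv_stop("'", name, "' must be a single finite number",
             class = "hrvrisk_config_error")
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper)
    hrv_stop("'", name, "' out of range", class = "hrvrisk_config_error")
  invisible(x)
}
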