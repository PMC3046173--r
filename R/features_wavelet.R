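#' Wavelet-packet energy and entropy features
#'
#' Decomposes the mean-subtracted NN series (zero-padded to a multiple of
#' `2^level`) into a full wavelet-packet tree with the DB4 mother wavelet
#' under periodic extension, and computes for every node of levels
#' 1..`level` (62 nodes at level 5) the mean coefficient energy
#' `E = mean(c^2)` and the Shannon entropy of the node's normalized
#' coefficient energies `S = -sum(p log p)` with `p_i = c_i^2 / sum(c^2)`
#' and `0 log 0 = 0`. Natural (filter-bank) node ordering; natural
#' logarithm.
#'
#' @param rr An [rr_series] with at least 64 intervals.
#' @param wavelet Mother wavelet (`"db4"` default, `"haar"` available).
#' @param level Decomposition depth (default 5).
#' @return Object of class `wp_features`: a list with `features` (named
#'   vector `wpE_L{l}N{i}` then `wpS_L{l}N{i}`), `nodes` (data frame with
#'   level, index, coefficient count, energy, entropy) and `norm2` (squared
#'   norm of the mean-subtracted input, for energy bookkeeping).
#' @export
wp_features <- function(rr, wavelet = "db4", level = 5L) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 2L^(level + 1L))
    hrv_stop("need at least ", 2L^(level + 1L),
             " intervals for a level-", level, " packet tree",
             class = "hrvrisk_validation_error")
  x <- x - mean(x)
  tree <- wp_decompose(x, level, wavelet)
  rows <- list()
  for (l in seq_len(level)) {
    for (i in seq_len(2L^l)) {
      cf <- tree[[l]][[i]]
      e2 <- cf^2
      tot <- sum(e2)
      s <- if (tot > 0) {
        p <- e2[e2 > 0] / tot
        -sum(p * log(p))
      } else 0
      rows[[length(rows) + 1L]] <-
        data.frame(level = l, index = i, n_coef = length(cf),
                   energy = mean(e2), entropy = s)
    }
  }
  nodes <- do.call(rbind, rows)
  feats <- c(
    stats::setNames(nodes$energy,
                    sprintf("wpE_L%dN%d", nodes$level, nodes$index)),
    stats::setNames(nodes$entropy,
                    sprintf("wpS_L%dN%d", nodes$level, nodes$index)))
  structure(list(features = feats, nodes = nodes, norm2 = sum(x^2),
                 wavelet = wavelet, level = level),
            class = "wp_features")
}

#' @export
print.wp_features <- function(x, ...) {
  cat(sprintf("<wp_features: %s level %d, %d nodes>\n",
              x$wavelet, x$level, nrow(x$nodes)))
  invisible(x)
}

#' Principal component analysis of a feature block
#'
#' Centered covariance eigendecomposition with components sorted by
#' eigenvalue (descending) and a deterministic sign convention: the loading
#' of largest magnitude in each component is positive. Used to compress the
#' redundant wavelet-packet feature block.
#'
#' @param feature_table Numeric matrix or data frame (records x features).
#' @param n_components Number of components to keep (default: all
#'   non-trivial ones; truncated with a warning when more are requested
#'   than `min(n_records - 1, n_features)` supports).
#' @return Object of class `pca_model` with orthonormal `components`
#'   (features x components), `explained_variance_ratio` and the centering
#'   `mean`.
#' @export
fit_pca <- function(feature_table, n_components = NULL) {
  x <- as.matrix(feature_table)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 1L)
    hrv_stop("PCA needs at least 2 records and 1 feature",
             class = "hrvrisk_validation_error")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  avail <- ncol(pc$rotation)
  k <- n_components %||% avail
  if (k > avail) {
    hrv_warn(sprintf("only %d components available; truncating from %d",
                     avail, k))
    k <- avail
  }
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(comp[, j]))
    if (comp[peak, j] < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- paste0("PC_", seq_len(k))
  structure(list(components = comp,
                 explained_variance_ratio =
                   if (total_var > 0) pc$sdev[seq_len(k)]^2 / total_var
                   else rep(0, k),
                 mean = pc$center),
            class = "pca_model")
}

#' Project a feature table onto a fitted PCA basis
#'
#' @param model A [fit_pca] model.
#' @param feature_table Numeric matrix or data frame with the same feature
#'   dimension the model was fitted on.
#' @return Matrix of projections, columns `PC_k`.
#' @export
pca_project <- function(model, feature_table) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(feature_table)
  storage.mode(x) <- "double"
  if (ncol(x) != nrow(model$components))
    hrv_stop("feature dimension (", ncol(x), ") does not match the model (",
             nrow(model$components), ")", class = "hrvrisk_schema_error")
  sweep(x, 2L, model$mean) %*% model$components
}
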