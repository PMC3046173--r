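# Periodized orthogonal wavelet filter bank.
#
# No wavelet package ships with the environments this package targets, and
# the transform here must be exactly orthogonal under periodic extension so
# that per-level energy bookkeeping is testable to floating-point accuracy,
# so the filter bank is implemented directly. Signals are zero-padded to a
# multiple of 2^level before analysis; zero padding leaves the squared norm
# unchanged, and even length at every split keeps the periodized transform
# orthonormal.

# Daubechies scaling (lowpass) coefficients, classic h0..h(L-1) order
.wt_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032)
)

wt_filter <- function(wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- .wt_filters[[wavelet]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)  # quadrature mirror highpass
  list(h = h, g = g)
}

# one periodized analysis step; length(x) must be even
wt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt$h)
  idx <- (outer(seq(0L, n - 2L, by = 2L), 0:(L - 1L), `+`) %% n) + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L, ncol = L)
  list(a = drop(xm %*% filt$h), d = drop(xm %*% filt$g))
}

# inverse of wt_step
wt_istep <- function(a, d, filt) {
  m <- length(a)
  n <- 2L * m
  x <- numeric(n)
  k2 <- 2L * (seq_len(m) - 1L)
  for (j in seq_along(filt$h)) {
    pos <- ((k2 + (j - 1L)) %% n) + 1L
    x[pos] <- x[pos] + filt$h[j] * a + filt$g[j] * d
  }
  x
}

pad_to_blocks <- function(x, level) {
  block <- 2L^level
  n2 <- as.integer(ceiling(length(x) / block) * block)
  c(x, numeric(n2 - length(x)))
}

# reconstruct a signal from its detail coefficients at levels 1..level only
# (approximation at the deepest level zeroed) -- the denoising pre-filter
# for R-peak detection
wt_detail_reconstruct <- function(x, level, wavelet = "haar") {
  filt <- wt_filter(wavelet)
  n0 <- length(x)
  x <- pad_to_blocks(x, level)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- wt_step(a, filt)
    a <- s$a
    details[[l]] <- s$d
  }
  a <- numeric(length(a))  # drop the lowpass branch (baseline / trend)
  for (l in rev(seq_len(level))) a <- wt_istep(a, details[[l]], filt)
  a[seq_len(n0)]
}

# full wavelet packet tree to `level`; returns list of levels, each a list
# of 2^l coefficient vectors in natural (filter-bank) order
wp_decompose <- function(x, level, wavelet = "db4") {
  filt <- wt_filter(wavelet)
  tree <- vector("list", level)
  nodes <- list(pad_to_blocks(x, level))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      s <- wt_step(nodes[[i]], filt)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    tree[[l]] <- nxt
    nodes <- nxt
  }
  tree
}
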