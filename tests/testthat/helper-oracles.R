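# Independent brute-force oracles used to validate the optimized
# implementations. These are written for clarity, not speed, and stay
# independent of the package's code paths.

# Pincus approximate entropy by direct template counting (self-matches in)
apen_brute <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    cc <- numeric(nm)
    for (i in seq_len(nm)) {
      cnt <- 0
      for (j in seq_len(nm)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      }
      cc[i] <- cnt / nm
    }
    mean(log(cc))
  }
  phi(m) - phi(m + 1)
}

# Richman-Moorman sample entropy by direct counting (self-matches out)
smen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  a_cnt <- 0
  b_cnt <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r)
        b_cnt <- b_cnt + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r)
        a_cnt <- a_cnt + 1
    }
  }
  if (a_cnt == 0 || b_cnt == 0) NA_real_ else -log(a_cnt / b_cnt)
}

# two-sample KS statistic by scanning the pooled ECDFs at every pooled value
ks_d_brute <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  max(vapply(ts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# AUC as the normalized Mann-Whitney U statistic (ties count one half)
auc_rank_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# generalized ESD by explicit iteration with t-quantile critical values
rosner_brute <- function(x, k_max, alpha) {
  n <- length(x)
  cur <- x
  removed_vals <- numeric(0)
  rs <- numeric(0)
  lams <- numeric(0)
  for (i in seq_len(k_max)) {
    s <- sd(cur)
    if (s == 0) break
    dev <- abs(cur - mean(cur)) / s
    j <- which.max(dev)
    rs[i] <- dev[j]
    ni <- n - i + 1
    tc <- qt(1 - alpha / (2 * ni), ni - 2)
    lams[i] <- (ni - 1) * tc / sqrt((ni - 2 + tc^2) * ni)
    removed_vals[i] <- cur[j]
    cur <- cur[-j]
  }
  k <- if (any(rs > lams)) max(which(rs > lams)) else 0
  sort(removed_vals[seq_len(k)])
}

# small labeled 2-D blob datasets for classifier capacity checks
make_blobs <- function(n_per = 30, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  data.frame(class = rep(c("N", "R"), each = n_per), f1 = x[, 1],
             f2 = x[, 2])
}

make_xor <- function(n_per = 15, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  lab <- c("N", "N", "R", "R")
  do.call(rbind, lapply(1:4, function(i) {
    data.frame(class = lab[i],
               f1 = rnorm(n_per, centers[i, 1], 0.4),
               f2 = rnorm(n_per, centers[i, 2], 0.4))
  }))
}
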