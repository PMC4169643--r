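# Independent reference implementations used to cross-check the package:
# written step-by-step from the defining formulas, structured differently
# from the package code paths they validate.

# Rosner's generalized ESD recursion, literal transcription: at step i the
# extreme studentized deviate of the remaining values is compared against
# the t-based critical value; outliers are the first `declared` removals.
oracle_esd <- function(x, r_max = 15L, alpha = 0.05) {
  n <- length(x)
  r_max <- min(r_max, n - 2L)  # t quantile needs >= 1 df at the last step
  active <- rep(TRUE, n)
  R <- lambda <- numeric(0)
  removed <- integer(0)
  for (i in seq_len(r_max)) {
    xs <- x[active]
    mu <- sum(xs) / length(xs)
    s2 <- sum((xs - mu)^2) / (length(xs) - 1)
    if (s2 <= 0) break
    devs <- abs(x - mu)
    devs[!active] <- -Inf
    k <- which.max(devs)
    R[i] <- devs[k] / sqrt(s2)
    p <- 1 - alpha / (2 * (n - i + 1))
    tq <- qt(p, n - i - 1)
    lambda[i] <- tq * (n - i) / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    removed[i] <- k
    active[k] <- FALSE
  }
  declared <- 0L
  for (i in seq_along(R)) if (R[i] > lambda[i]) declared <- i
  list(n_outliers = declared, outlier_indices = removed[seq_len(declared)],
       R = R, lambda = lambda)
}

# BH step-up from the definition: sort descending, running minimum of
# p * m / rank, cap at 1, map back.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (pos in seq_len(m)) {
    i <- ord[pos]
    rank_i <- m - pos + 1L
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- min(1, running)
  }
  adj
}

# Hypergeometric upper tail by direct enumeration of the point masses.
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  mass <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(mass[ks >= k])
}
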