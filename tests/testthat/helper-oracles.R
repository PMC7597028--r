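# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately written from first principles and
# share no code with the functions they test.

# Ordinary pooled-variance two-sample t per feature.
pooled_t_oracle <- function(m, idx1, idx2) {
  t(apply(m, 1L, function(v) {
    x <- v[idx1]; y <- v[idx2]
    n1 <- length(x); n2 <- length(y)
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
    tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    c(delta = mean(y) - mean(x), t = tt)
  }))
}

# Benjamini-Hochberg step-up by hand: p * n / rank with a cumulative
# minimum from the largest p downward, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# TMM factors computed directly from the trimmed-mean definition:
# reference = library whose 75th-percentile count fraction is closest to the
# mean; per library, inverse-asymptotic-variance weighted mean of gene-wise
# log2 ratios after trimming 30% on M and 5% on A; rescaled to geometric
# mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib[j]
    refv <- counts[, ref] / lib[ref]
    pos <- obs > 0 & refv > 0
    m_val <- log2(obs[pos] / refv[pos])
    a_val <- 0.5 * log2(obs[pos] * refv[pos])
    w <- (lib[j] - counts[pos, j]) / (lib[j] * counts[pos, j]) +
      (lib[ref] - counts[pos, ref]) / (lib[ref] * counts[pos, ref])
    n <- length(m_val)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m_val) >= lo_m & rank(m_val) <= hi_m &
      rank(a_val) >= lo_a & rank(a_val) <= hi_a
    2^(sum(m_val[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Kaplan-Meier product-limit by direct counting.
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_i <- sum(time >= tt[i])
    d_i <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(times = tt, surv = surv)
}

# Log-rank O-E / V sums by direct counting over distinct event times.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
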