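# Independent brute-force oracles used across the suite.  These are
# kept deliberately naive (direct formulas, exhaustive recomputation)
# so they share no code path with the implementation they check.

# Pearson r and two-sided p straight from the covariance formula and
# the t distribution.
oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE))
}

# Greedy Ward agglomeration recomputing every candidate cluster's
# within-cluster sum of squares from scratch at each step; returns the
# sequence of SS increments.
oracleWard <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  ssOf <- function(idx) {
    if (length(idx) == 1L) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters))
      if (a < b) {
        inc <- ssOf(c(clusters[[a]], clusters[[b]])) -
          ssOf(clusters[[a]]) - ssOf(clusters[[b]])
        if (inc < best[1]) best <- c(inc, a, b)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Benjamini-Hochberg step-up recursion written out directly.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Log-rank statistic from explicitly enumerated risk tables.
oracleLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

panel60 <- simPanel()
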