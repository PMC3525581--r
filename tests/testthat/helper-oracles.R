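# Independent oracle implementations, deliberately coded from first
# principles (explicit loops, no shared helpers with the package).

# brute-force silhouette-mean score of a two-group 1-D configuration
oracle_sdes <- function(male, female) {
  pts <- c(male, female)
  grp <- c(rep("m", length(male)), rep("f", length(female)))
  total <- 0
  for (i in seq_along(pts)) {
    own <- pts[grp == grp[i]]
    oth <- pts[grp != grp[i]]
    # a: average distance to the other own-group points
    a <- 0
    if (length(own) > 1) {
      ssum <- 0
      for (y in own) ssum <- ssum + abs(pts[i] - y)
      a <- ssum / (length(own) - 1)   # excludes the zero self-distance
    }
    bsum <- 0
    for (z in oth) bsum <- bsum + abs(pts[i] - z)
    b <- bsum / length(oth)
    s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    total <- total + s
  }
  total / length(pts)
}

# explicit running-sum enrichment score for hit positions in a ranked list;
# magnitude ties (to 1e-12) resolve to the extremum reached first
oracle_es <- function(scores_desc, hit_positions, weight = 1) {
  N <- length(scores_desc)
  k <- length(hit_positions)
  wsum <- 0
  for (p in hit_positions) wsum <- wsum + abs(scores_desc[p])^weight
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (i %in% hit_positions) {
      inc <- if (wsum == 0) 1 / k else abs(scores_desc[i])^weight / wsum
      rs <- rs + inc
    } else {
      rs <- rs - 1 / (N - k)
    }
    if (abs(rs) > abs(best) + 1e-12) best <- rs
  }
  best
}

# two-sided p-value by numeric integration of the t density
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tstat), Inf)$value
}

# tricube-weighted local linear regression evaluated at each x (no
# robustness iterations; exact for data lying on a straight line)
oracle_local_linear <- function(x, y, span) {
  n <- length(x)
  q <- max(2L, ceiling(span * n))
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(0, (1 - pmin(1, d / h)^3))^3
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    fitted[i] <- fit$coefficients[1] + fit$coefficients[2] * x[i]
  }
  fitted
}

# two-pass mean / sample-SD standardisation
oracle_zscore <- function(v) {
  m <- sum(v) / length(v)
  ss <- 0
  for (u in v) ss <- ss + (u - m)^2
  sdv <- sqrt(ss / (length(v) - 1))
  (v - m) / sdv
}
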