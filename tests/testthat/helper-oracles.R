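# Independent brute-force reference implementations used as oracles. These
# deliberately avoid the package's vectorized code paths: binning is a
# per-point linear scan over ring boundaries and the entropy is the literal
# term-by-term sum.

nde_bruteforce <- function(series, rings, delay = 1L) {
  x <- series - min(series)
  n <- length(x)
  d <- numeric(n - delay)
  for (j in seq_len(n - delay)) d[j] <- sqrt(x[j]^2 + x[j + delay]^2)
  l_max <- max(d)
  if (l_max == 0) return(0)
  dl <- l_max / rings
  counts <- integer(rings)
  for (dist in d) {
    k <- 1L
    while (k < rings && dist >= k * dl) k <- k + 1L
    counts[k] <- counts[k] + 1L
  }
  p <- counts / length(d)
  s <- 0
  for (k in seq_len(rings)) {
    qk <- 1 + l_max - (k - 1) * dl - dl / 2
    if (p[k] > 0) s <- s + (p[k] - p[k]^qk) / (qk - 1)
  }
  s
}

jt_bruteforce <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (a in groups[[i]]) {
        for (b in groups[[j]]) {
          if (a < b) jt <- jt + 1 else if (a == b) jt <- jt + 0.5
        }
      }
    }
  }
  jt
}

# Points realizing a given ring-occupancy probability vector: `n_points`
# scatter points placed on the x-axis at the center of each ring, with the
# last occupied point pinned to l_max so the partition reproduces `p` exactly.
points_for_p <- function(p, l_max, n_points) {
  rings <- length(p)
  counts <- round(p * n_points)
  stopifnot(sum(counts) == n_points, counts[rings] >= 1)
  dl <- l_max / rings
  radii <- rep((seq_len(rings) - 0.5) * dl, counts)
  radii[length(radii)] <- l_max
  cbind(x = radii, y = 0)
}
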