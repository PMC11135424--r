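# Independent oracles used across tests. These deliberately avoid the code
# paths (and where possible the library routines) they are checked against.

# Two-sided Fisher probability by exhaustive enumeration of all tables with
# the observed margins, from factorial arithmetic only.
fisherOracleP <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[xs == a] * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct summation.
hyperUpperOracle <- function(k, set_size, universe, draws) {
  xs <- k:min(set_size, draws)
  sum(exp(lchoose(set_size, xs) + lchoose(universe - set_size, draws - xs) -
            lchoose(universe, draws)))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of the
# pooled ranks to group A (tie-free samples only).
wilcoxOracleP <- function(a, b) {
  n <- length(a)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n)])
  ws <- apply(combn(length(ranks), n), 2, function(ix) sum(ranks[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Binomial LRT statistic by grid-search maximization of the log-likelihoods
# (independent of the closed-form MLE route).
lrtOracleStat <- function(i1, s1, i2, s2, grid_n = 20001) {
  grid <- seq(1e-6, 1 - 1e-6, length.out = grid_n)
  ll <- function(i, s) i * log(grid) + s * log(1 - grid)
  2 * (max(ll(i1, s1)) + max(ll(i2, s2)) - max(ll(i1, s1) + ll(i2, s2)))
}

# Brute-force PWM scan: rescore every offset with an explicit loop.
scanOracle <- function(seq_chr, mat, bg, threshold = 0.8, pseudo = 1e-4) {
  p <- (mat + pseudo) / (1 + 4 * pseudo)
  bgn <- (bg + pseudo) / (1 + 4 * pseudo)
  lo <- log2(p / bgn)
  chars <- strsplit(seq_chr, "")[[1]]
  L <- ncol(lo)
  cutoff <- threshold * sum(apply(lo, 2, max))
  hits <- integer(0)
  scores <- numeric(0)
  for (t in seq_len(length(chars) - L + 1)) {
    s <- 0
    ok <- TRUE
    for (j in seq_len(L)) {
      base <- chars[t + j - 1]
      ri <- match(base, c("A", "C", "G", "T"))
      if (is.na(ri)) { ok <- FALSE; break }
      s <- s + lo[ri, j]
    }
    if (ok && s >= cutoff) {
      hits <- c(hits, t)
      scores <- c(scores, s)
    }
  }
  data.frame(pos = hits, score = scores)
}
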