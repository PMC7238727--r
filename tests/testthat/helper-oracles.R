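# Independent oracles used across the suite. Deliberately naive code:
# these must not share logic with the implementation they check.

# All permutations of 1..n as rows (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Umbrella pair-count statistic by explicit double loops over observations.
naive_umbrella_stat <- function(values, groups, pairs) {
  s <- 0
  for (r in seq_len(nrow(pairs))) {
    a <- values[groups == pairs$lo[r]]
    b <- values[groups == pairs$hi[r]]
    for (x in a) for (y in b) {
      if (x < y) s <- s + pairs$w[r]
      if (x == y) s <- s + 0.5 * pairs$w[r]
    }
  }
  s
}

# Exact one-sided umbrella p by brute force over all n! position
# permutations (independent of the package's assignment enumeration).
brute_umbrella_p <- function(values, groups, peak_group) {
  pairs <- dielphage:::umbrella_pairs(max(groups), peak_group)
  a_obs <- naive_umbrella_stat(values, groups, pairs)
  P <- all_perms(length(values))
  a_all <- apply(P, 1, function(ix) naive_umbrella_stat(values[ix], groups, pairs))
  mean(a_all >= a_obs - 1e-9)
}

# Deterministic constant-depth series used in several tests.
flat_series <- function(n = 44, count = 5, total = 1000, interval = 4) {
  list(counts = rep(count, n),
       times = interval * (seq_len(n) - 1),
       totals = rep(total, n))
}

# Poisson cosinor series with known truth.
rhythmic_series <- function(n = 44, depth = 1e4, rel = 1e-3, amp = 0.5,
                            phase = 6, interval = 4, sigma = 0.2) {
  tm <- interval * (seq_len(n) - 1)
  N <- if (sigma > 0) round(stats::rlnorm(n, log(depth), sigma)) else rep(depth, n)
  x <- stats::rpois(n, N * rel * (1 + amp * cos(2 * pi * (tm - phase) / 24)))
  list(counts = x, times = tm, totals = N, phase = phase, amp = amp)
}

# Smallest circular difference in hours (period 24).
circ_diff <- function(a, b) {
  d <- (a - b) %% 24
  pmin(d, 24 - d)
}
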