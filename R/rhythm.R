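#' Eligibility of a count series for the periodicity screen
#'
#' A gene or ortholog enters the periodicity test only if it accumulated at
#' least `min_total` transcripts over the sampling period; the default
#' threshold equals the number of time points (an average of one transcript
#' per sampling time).
#'
#' @param counts Integer vector of per-time-point transcript counts.
#' @param min_total Minimum summed count; defaults to `length(counts)`.
#' @return `TRUE` if the series is eligible.
#' @examples
#' eligibility(rep(1, 44))        # TRUE
#' eligibility(c(rep(1, 43), 0))  # FALSE
#' @export
eligibility <- function(counts, min_total = length(counts)) {
  sum(counts) >= min_total
}

#' Per-time-point relative transcript abundance
#'
#' @param counts Integer vector of transcript counts `x_t`.
#' @param totals Positive integer vector of library totals `N_t`.
#' @return `counts / totals`, elementwise.
#' @export
relative_abundance <- function(counts, totals) {
  stopifnot(length(counts) == length(totals))
  if (any(totals <= 0)) stop("all totals must be positive", call. = FALSE)
  counts / totals
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); adjusted values are monotone and clamped to 1.
#' `NA` entries are passed through.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values of the same length.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  out <- p
  ok <- !is.na(p)
  # adjust across the tests actually performed; NA (untested) entries pass
  # through without inflating the correction
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# --- umbrella statistic machinery ------------------------------------------

# Weighted ordered group pairs (lo expected below hi) for an umbrella with
# peak at group `peak` among groups 1..G arranged circularly in phase order.
# The rising limb runs from the antipodal trough up to the peak, the falling
# limb from the peak back down to the trough (wrapping); the trough-peak
# pair lies on both limbs and gets weight 2.
umbrella_pairs <- function(G, peak) {
  h <- G %/% 2
  trough <- ((peak - 1 + h) %% G) + 1
  rising <- ((trough - 1 + 0:(G - h)) %% G) + 1   # trough ... peak
  falling <- ((peak - 1 + 0:h) %% G) + 1          # peak ... trough
  rp <- t(utils::combn(rising, 2))                 # (lo, hi) along rising
  fp <- t(utils::combn(falling, 2))[, 2:1, drop = FALSE]  # (lo, hi) falling
  pairs <- rbind(rp, fp)
  key <- paste(pairs[, 1], pairs[, 2])
  w <- as.vector(table(key)[unique(key)])
  uk <- do.call(rbind, strsplit(unique(key), " "))
  data.frame(lo = as.integer(uk[, 1]), hi = as.integer(uk[, 2]), w = w)
}

# Mann-Whitney pair count sum: A = sum_w w * [#(x_lo < x_hi) + 0.5 #(=)].
umbrella_stat <- function(values, groups, pairs) {
  G <- max(pairs$lo, pairs$hi)
  by_g <- split(values, factor(groups, levels = seq_len(G)))
  s <- 0
  for (r in seq_len(nrow(pairs))) {
    a <- by_g[[pairs$lo[r]]]
    b <- by_g[[pairs$hi[r]]]
    cmp <- outer(a, b, "<")
    eq <- outer(a, b, "==")
    s <- s + pairs$w[r] * (sum(cmp) + 0.5 * sum(eq))
  }
  s
}

# Moments of h(V_a, V_b) = 1(V_a < V_b) + 0.5 * 1(V_a = V_b) over ordered
# distinct draws (without replacement) from the observed value multiset.
# Used for the exact permutation mean/variance of the umbrella statistic,
# with ties handled exactly.
value_moments <- function(values) {
  cc <- as.numeric(table(values))
  N <- sum(cc)
  cum <- cumsum(cc)
  L <- c(0, cum[-length(cum)])   # values strictly below each unique value
  Gt <- N - cum                  # strictly above
  T2 <- sum(cc * (cc - 1))
  T3 <- sum(cc * (cc - 1) * (cc - 2))
  D2 <- N * (N - 1)
  D3 <- D2 * (N - 2)
  q_tt <- 0.5 - T2 / (4 * D2)
  q_rev <- T2 / (4 * D2)
  q_s <- (sum(cc * Gt * (Gt - 1)) + sum(cc * (cc - 1) * Gt) + 0.25 * T3) / D3
  q_t <- (sum(cc * L * (L - 1)) + sum(cc * (cc - 1) * L) + 0.25 * T3) / D3
  q_m <- (sum(cc * L * Gt) + 0.5 * sum(cc * (cc - 1) * L) +
            0.5 * sum(cc * (cc - 1) * Gt) + 0.25 * T3) / D3
  q_d <- if (N >= 4) {
    ((D2 / 2)^2 - D2 * (q_tt + q_rev) - D3 * (q_s + q_t + 2 * q_m)) /
      (D3 * (N - 3))
  } else {
    NA_real_
  }
  list(N = N, q_tt = q_tt, q_rev = q_rev, q_s = q_s, q_t = q_t,
       q_m = q_m, q_d = q_d)
}

# Exact permutation mean and variance of the weighted umbrella statistic.
# E[A^2] is assembled by classifying every ordered pair of position pairs
# by its overlap pattern (identical, reversed, shared first/second
# position, chained, disjoint) and weighting with the corresponding value
# moment; exact under ties.
umbrella_moments <- function(values, groups, pairs) {
  n_g <- as.numeric(table(factor(groups, levels = seq_len(max(pairs$hi,
                                                              pairs$lo)))))
  qm <- value_moments(values)
  ea <- sum(pairs$w * n_g[pairs$lo] * n_g[pairs$hi]) / 2
  ea2 <- 0
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$lo[i]; v <- pairs$hi[i]; w1 <- pairs$w[i]
    nu <- n_g[u]; nv <- n_g[v]
    for (j in seq_len(nrow(pairs))) {
      u2 <- pairs$lo[j]; v2 <- pairs$hi[j]; w2 <- pairs$w[j]
      nu2 <- n_g[u2]; nv2 <- n_g[v2]
      I <- if (u == u2 && v == v2) nu * nv else 0
      R <- if (u == v2 && v == u2) nu * nv else 0
      SF <- if (u == u2) nu * (nv * nv2 - (v == v2) * nv) else 0
      SS <- if (v == v2) nv * (nu * nu2 - (u == u2) * nu) else 0
      C1 <- if (v == u2) {
        nv * nu * nv2 - (v2 == v) * nv * nu - (v2 == u) * nv * nu
      } else 0
      C2 <- if (u == v2) {
        nu * nv * nu2 - (u2 == u) * nu * nv - (u2 == v) * nu * nv
      } else 0
      D <- nu * nv * nu2 * nv2 - I - R - SF - SS - C1 - C2
      m <- I * qm$q_tt + R * qm$q_rev + SF * qm$q_s + SS * qm$q_t +
        (C1 + C2) * qm$q_m + D * qm$q_d
      ea2 <- ea2 + w1 * w2 * m
    }
  }
  list(mean = ea, var = max(ea2 - ea^2, 0))
}

# Map sampling times to circular phase groups: counts at the same clock
# phase on different days are pooled.
phase_groups <- function(times, period_h = 24, interval_h = 4) {
  idx <- floor(((times %% period_h) + 1e-9) / interval_h)
  match(idx, sort(unique(idx)))
}

#' Rank-based umbrella test for a 24-h rhythm in a count series
#'
#' Screens a longitudinal count series for a diel rhythm. Observations are
#' normalized to their library totals, pooled into circular phase groups
#' (same clock phase on different days), and tested against umbrella
#' alternatives: for each candidate peak group, a Jonckheere-Terpstra-type
#' statistic sums Mann-Whitney pair counts along the rising limb from the
#' antipodal trough to the peak and the falling limb back to the trough.
#' Each candidate's one-sided p comes from a normal approximation whose
#' null mean and variance are computed exactly under the permutation
#' distribution (ties handled exactly); the reported p is the smallest
#' candidate p Bonferroni-multiplied by the number of candidate profiles
#' and clamped to 1. The procedure is a rank-based umbrella screen in the
#' spirit of published non-parametric rhythm detectors, not a clone of any
#' of them.
#'
#' @param counts Integer vector of transcript counts per time point.
#' @param times Sampling times in hours (same length).
#' @param totals Optional library totals `N_t`; when given, `counts/totals`
#'   is ranked instead of raw counts.
#' @param period_h Period of the tested rhythm in hours (default 24).
#' @param interval_h Width of a phase group in hours (default 4, giving 6
#'   groups for a 24-h period).
#' @return A list with `statistic` (the umbrella pair-count statistic at
#'   the best candidate peak), `z` (its standardized value), `peak_group`
#'   (1-based index of the best candidate phase group), `n_groups`, and
#'   `p` (Bonferroni-adjusted minimum candidate p). Degenerate series
#'   (all values tied) give `p = 1`.
#' @examples
#' tm <- seq(0, 92, by = 4)
#' x <- rpois(length(tm), 20 * (1 + 0.8 * cos(2 * pi * (tm - 8) / 24)))
#' umbrella_rain_test(x, tm)$p
#' @export
umbrella_rain_test <- function(counts, times, totals = NULL,
                               period_h = 24, interval_h = 4) {
  stopifnot(length(counts) == length(times))
  values <- if (is.null(totals)) counts else relative_abundance(counts, totals)
  grp <- phase_groups(times, period_h, interval_h)
  G <- max(grp)
  if (G < 2) stop("need at least 2 distinct phase groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, z = 0, peak_group = NA_integer_,
                n_groups = G, p = 1))
  }
  stats_k <- numeric(G)
  p_k <- numeric(G)
  for (k in seq_len(G)) {
    pr <- umbrella_pairs(G, k)
    mo <- umbrella_moments(values, grp, pr)
    a <- umbrella_stat(values, grp, pr)
    stats_k[k] <- a
    # standard 0.5 continuity correction for the pair-count lattice
    p_k[k] <- if (mo$var <= 0) 1 else {
      stats::pnorm((a - 0.5 - mo$mean) / sqrt(mo$var), lower.tail = FALSE)
    }
  }
  best <- which.min(p_k)
  list(statistic = stats_k[best],
       z = if (p_k[best] < 1) stats::qnorm(p_k[best], lower.tail = FALSE) else 0,
       peak_group = best,
       n_groups = G,
       p = min(1, G * p_k[best]))
}

#' Exact permutation p value of the umbrella statistic
#'
#' Small-sample oracle for [umbrella_rain_test()]: enumerates every
#' assignment of the observed values to the group layout and returns the
#' exact one-sided tail probability of the umbrella statistic for a single
#' candidate peak group. Intended for at most 10 observations.
#'
#' @param values Numeric observations.
#' @param groups Integer group index per observation (1..G, circular phase
#'   order).
#' @param peak_group Candidate peak group.
#' @return Exact `P(A >= A_obs)` under the permutation null.
#' @examples
#' exact_umbrella_p(c(1, 2, 3, 2.5, 1.5, 0.5), 1:6, peak_group = 3)
#' @export
exact_umbrella_p <- function(values, groups, peak_group) {
  n <- length(values)
  stopifnot(length(groups) == n)
  if (n > 10) stop("use approximation", call. = FALSE)
  G <- max(groups)
  pairs <- umbrella_pairs(G, peak_group)
  sizes <- as.integer(table(factor(groups, levels = seq_len(G))))
  a_obs <- umbrella_stat(values, groups, pairs)
  # enumerate distinct assignments of value indices to groups (order within
  # a group is irrelevant to the statistic); H holds pairwise h(x_i, x_j)
  H <- outer(values, values, "<") + 0.5 * outer(values, values, "==")
  count_ge <- 0L
  count_all <- 0L
  members <- vector("list", G)
  recurse <- function(remaining, g) {
    if (g > G) {
      a <- 0
      for (r in seq_len(nrow(pairs))) {
        a <- a + pairs$w[r] *
          sum(H[members[[pairs$lo[r]]], members[[pairs$hi[r]]]])
      }
      count_all <<- count_all + 1L
      if (a >= a_obs - 1e-9) count_ge <<- count_ge + 1L
      return(invisible())
    }
    if (sizes[g] == 0) {
      members[[g]] <<- integer()
      recurse(remaining, g + 1)
      return(invisible())
    }
    # index combn over positions of `remaining` (combn treats a scalar
    # first argument as seq_len)
    picks <- utils::combn(seq_along(remaining), sizes[g], simplify = FALSE)
    for (ip in picks) {
      p <- remaining[ip]
      members[[g]] <<- p
      recurse(remaining[-ip], g + 1)
    }
    invisible()
  }
  recurse(seq_len(n), 1)
  count_ge / count_all
}

#' Screen gene/ortholog count series for 24-h periodicity
#'
#' Tidy front end to the rhythmicity screen: applies the eligibility rule,
#' runs the umbrella rank test on every eligible series, and controls the
#' false discovery rate across the eligible tests with Benjamini-Hochberg.
#'
#' @param counts Long tibble with columns `unit_id` (or `gene_id`),
#'   `sample`, `count`.
#' @param totals Tibble with columns `sample`, `time_h`, `total`.
#' @param period_h,interval_h Passed to [umbrella_rain_test()].
#' @param min_total Eligibility threshold; defaults to the number of time
#'   points.
#' @param fdr Adjusted-p threshold declaring significant periodicity
#'   (default 0.1).
#' @return A tibble of class `diel_rhythm` with one row per unit:
#'   `unit_id`, `n_transcripts`, `eligible`, `statistic`, `peak_group`,
#'   `p_raw`, `p_fdr`, `periodic`. Ineligible units carry `NA` test fields
#'   and `periodic = FALSE`. Extra identifier columns (e.g. `group`) are
#'   carried through.
#' @examples
#' sim <- simulate_counts(diel_design(24, 4), gene_table(2, 2), 2e3, seed = 1)
#' detect_rhythms(sim$counts, sim$totals)
#' @export
detect_rhythms <- function(counts, totals, period_h = 24, interval_h = 4,
                           min_total = NULL, fdr = 0.1) {
  counts <- normalize_id(counts)
  if (is.null(min_total)) min_total <- nrow(totals)
  carry <- intersect("group", names(counts))
  res <- counts |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::group_by(.data$unit_id,
                    !!!rlang::syms(carry)) |>
    dplyr::summarise(
      n_transcripts = sum(.data$count),
      eligible = eligibility(.data$count, min_total),
      test = list(if (eligibility(.data$count, min_total)) {
        umbrella_rain_test(.data$count, .data$time_h, .data$total,
                           period_h, interval_h)
      } else {
        list(statistic = NA_real_, peak_group = NA_integer_, p = NA_real_)
      }),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = purrr::map_dbl(.data$test, "statistic"),
      peak_group = purrr::map_int(.data$test,
                                  ~ as.integer(.x$peak_group %||% NA)),
      p_raw = purrr::map_dbl(.data$test, "p")
    ) |>
    dplyr::select(-"test")
  res$p_fdr <- fdr_bh(res$p_raw)
  res$periodic <- !is.na(res$p_fdr) & res$p_fdr < fdr
  class(res) <- c("diel_rhythm", class(res))
  attr(res, "fdr") <- fdr
  res
}

# Accept either `unit_id` or `gene_id` as the series identifier.
normalize_id <- function(counts) {
  if (!"unit_id" %in% names(counts)) {
    if ("gene_id" %in% names(counts)) {
      counts <- dplyr::rename(counts, unit_id = "gene_id")
    } else {
      stop("`counts` needs a `unit_id` or `gene_id` column", call. = FALSE)
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
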