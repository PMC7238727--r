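test_that("eligibility needs one transcript per time point on average", {
  expect_false(eligibility(c(rep(1, 43), 0)))       # 43 over 44 points
  expect_true(eligibility(rep(1, 44)))              # exactly 44
  expect_true(eligibility(rep(1, 10)))              # 10 over 10 points
  expect_true(eligibility(c(100, rep(0, 43))))      # threshold is the sum
})

test_that("relative abundance is the elementwise count/total ratio", {
  expect_equal(relative_abundance(2, 200), 0.01)
  expect_equal(relative_abundance(c(3, 4), c(3, 4)), c(1, 1))
  x <- c(2, 5, 9); N <- c(100, 200, 300)
  expect_equal(relative_abundance(x, 2 * N), relative_abundance(x, N) / 2)
  expect_error(relative_abundance(1, 0), "positive")
})

test_that("BH adjustment matches the step-up rule and never decreases p", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  expect_true(all(fdr_bh(p) >= p))
  expect_equal(fdr_bh(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("constant series carry no ordering signal (p = 1)", {
  tm <- 4 * (0:23)
  r <- umbrella_rain_test(rep(5, 24), tm)
  expect_equal(r$p, 1)
  # constant relative abundance with varying counts is also degenerate
  N <- rep(c(100, 200), 12)
  r2 <- umbrella_rain_test(rep(c(1, 2), 12), tm, N)
  expect_equal(r2$p, 1)
})

test_that("perfect umbrella order attains the maximum statistic and the enumerated p", {
  vals <- c(1, 2, 3, 2.5, 1.5, 0.5)  # peak at group 3 of 6
  tm <- 4 * (0:5)
  r <- umbrella_rain_test(vals, tm)
  pr <- dielphage:::umbrella_pairs(6, 3)
  expect_equal(r$statistic, sum(pr$w))   # every expected pair satisfied
  expect_equal(r$peak_group, 3)
  p_exact <- exact_umbrella_p(vals, 1:6, 3)
  expect_equal(p_exact, brute_umbrella_p(vals, 1:6, 3))
  # orderings attaining the joint maximum: both limb chains fully satisfied;
  # extremes fixed, remaining 4 values split 2/2 across the limbs
  expect_equal(p_exact, choose(4, 2) / factorial(6))
})

test_that("exact umbrella p equals brute-force enumeration, ties included", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(5:7, 1)
    G <- sample(3:4, 1)
    grp <- sort(rep_len(seq_len(G), n))
    vals <- sample(1:3, n, replace = TRUE)
    k <- sample(G, 1)
    expect_equal(exact_umbrella_p(vals, grp, k),
                 brute_umbrella_p(vals, grp, k))
  }
  expect_error(exact_umbrella_p(rep(1, 11), rep(1:2, length.out = 11), 1),
               "use approximation")
})

test_that("anti-ordered and all-tied data give large exact p", {
  # anti-umbrella: trough where the peak is hypothesized
  vals <- c(3, 2, 1, 1.5, 2.5, 3.5)
  p <- exact_umbrella_p(vals, 1:6, 3)
  expect_equal(p, brute_umbrella_p(vals, 1:6, 3))
  expect_gt(p, 0.99)
  expect_equal(exact_umbrella_p(rep(2, 4), c(1, 1, 2, 2), 1), 1)
})

test_that("permutation moments of the umbrella statistic are exact", {
  set.seed(17)
  for (i in 1:3) {
    n <- sample(6:7, 1)
    G <- 3
    grp <- sample(rep_len(seq_len(G), n))
    vals <- sample(1:3, n, replace = TRUE)
    pr <- dielphage:::umbrella_pairs(G, sample(G, 1))
    mo <- dielphage:::umbrella_moments(vals, grp, pr)
    P <- all_perms(n)
    a_all <- apply(P, 1, function(ix) naive_umbrella_stat(vals[ix], grp, pr))
    expect_equal(mo$mean, mean(a_all))
    expect_equal(mo$var, mean(a_all^2) - mean(a_all)^2)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(4)
  tm <- 4 * (0:43)
  x <- rpois(44, 10 * (1 + 0.6 * cos(2 * pi * (tm - 9) / 24)))
  r1 <- umbrella_rain_test(x, tm)
  r2 <- umbrella_rain_test(exp(x / 5), tm)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("a strong synthetic rhythm is detected and pooled across days", {
  set.seed(12)
  tm <- 4 * (0:43)
  N <- round(rlnorm(44, log(1e4), 0.2))
  x <- rpois(44, N * 1e-3 * (1 + 0.8 * cos(2 * pi * (tm - 14) / 24)))
  r <- umbrella_rain_test(x, tm, N)
  expect_lt(r$p, 0.01)
  expect_equal(r$n_groups, 6)
  # the winning peak group should sit near 14 h (group of clock phase 12-16)
  expect_equal(r$peak_group, 4)
})

test_that("detect_rhythms screens, adjusts and flags per unit", {
  set.seed(9)
  d <- diel_design()
  g <- gene_table(4, 4, amplitude_ratio = 0.8)
  g$base_rel_abundance[8] <- 1e-6   # stays below the eligibility threshold
  sim <- simulate_counts(d, g, 1e4, seed = 33)
  res <- detect_rhythms(sim$counts, sim$totals)
  expect_s3_class(res, "diel_rhythm")
  expect_equal(nrow(res), 8)
  ineligible <- dplyr::filter(res, !eligible)
  expect_true(all(is.na(ineligible$p_raw)))
  expect_true(all(!ineligible$periodic))
  called <- res$unit_id[res$periodic]
  expect_setequal(called, g$gene_id[g$rhythmic])
  expect_true(all(res$p_fdr >= res$p_raw, na.rm = TRUE))
})
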