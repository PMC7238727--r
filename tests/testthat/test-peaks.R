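test_that("peak time follows the quadrant-safe arctangent form", {
  expect_equal(peak_time(0, 1), 6)
  expect_equal(peak_time(1, 0), 0)
  expect_equal(peak_time(1, 1), 3)
  expect_equal(peak_time(-1, 0), 12)
  expect_equal(peak_time(0, -1), 18)
  expect_error(peak_time(0, 0), "undefined phase")
})

test_that("constant relative abundance collapses to the intercept model", {
  s <- flat_series()
  fit <- fit_harmonic_poisson(s$counts, s$times, s$totals)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["alpha"]]), 1e-6)
  expect_lt(abs(fit$coef[["beta"]]), 1e-6)
  expect_equal(fit$coef[["c"]], log(5 / 1000), tolerance = 1e-8)
  expect_equal(lrt_significance(fit), 1, tolerance = 1e-6)
})

test_that("IRLS coefficients agree with an independent GLM fit", {
  set.seed(61)
  for (i in 1:5) {
    s <- rhythmic_series(amp = runif(1, 0.2, 0.8), phase = runif(1, 0, 24))
    fit <- fit_harmonic_poisson(s$counts, s$times, s$totals)
    g <- stats::glm(
      s$counts ~ cos(2 * pi * s$times / 24) + sin(2 * pi * s$times / 24),
      family = stats::poisson(), offset = log(s$totals)
    )
    expect_equal(unname(fit$coef), unname(stats::coef(g)), tolerance = 1e-7)
    a <- stats::anova(g, test = "Chisq")
    # single-term chi-squared on 2 df equals the package LRT
    lrt_glm <- stats::pchisq(g$null.deviance - g$deviance, 2,
                             lower.tail = FALSE)
    expect_equal(lrt_significance(fit), lrt_glm, tolerance = 1e-8)
  }
})

test_that("scaling all library totals shifts only the intercept", {
  set.seed(62)
  s <- rhythmic_series()
  f1 <- fit_harmonic_poisson(s$counts, s$times, s$totals)
  f2 <- fit_harmonic_poisson(s$counts, s$times, 10 * s$totals)
  expect_equal(f2$coef[["c"]], f1$coef[["c"]] - log(10), tolerance = 1e-8)
  expect_equal(f2$coef[["alpha"]], f1$coef[["alpha"]], tolerance = 1e-8)
  expect_equal(f2$coef[["beta"]], f1$coef[["beta"]], tolerance = 1e-8)
})

test_that("rotating the time origin rotates the peak and keeps amplitude", {
  set.seed(63)
  s <- rhythmic_series(amp = 0.6, phase = 10)
  f1 <- fit_harmonic_poisson(s$counts, s$times, s$totals)
  for (shift in c(3, 7.5, 23)) {
    f2 <- fit_harmonic_poisson(s$counts, s$times + shift, s$totals)
    expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-8)
    expect_equal(f2$t_peak_h, (f1$t_peak_h + shift) %% 24, tolerance = 1e-6)
  }
})

test_that("degenerate series are rejected with clear errors", {
  expect_error(fit_harmonic_poisson(rep(0, 44), 4 * (0:43), rep(100, 44)),
               "all counts are zero")
  expect_error(fit_harmonic_poisson(1:3, c(0, 4, 8), rep(10, 3)),
               "at least 4")
  expect_error(fit_harmonic_poisson(1:4, 4 * (0:3), c(0, 1, 1, 1)),
               "positive")
})

test_that("chi-squared significance of fit behaves at its landmarks", {
  # a deviance drop of 5.991 on 2 df sits at p ~= 0.05
  expect_equal(stats::pchisq(5.991, 2, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  fake <- list(null_deviance = 10, deviance = 10)
  expect_equal(lrt_significance(fake), 1)
  fake2 <- list(null_deviance = 15.991, deviance = 10)
  expect_equal(lrt_significance(fake2), 0.05, tolerance = 1e-3)
})

test_that("jackknife enumerates every delete-d subsample", {
  expect_equal(jackknife_subsample_count(44, 2), 946)
  expect_equal(jackknife_subsample_count(4, 2), 6)
  for (n in c(5, 10, 37, 50)) {
    expect_equal(jackknife_subsample_count(n, 1), n)
    expect_equal(jackknife_subsample_count(n, 2), n * (n - 1) / 2)
  }
  set.seed(64)
  s <- rhythmic_series(n = 8, depth = 1e4, amp = 0.6)
  jk <- jackknife_ci(s$counts, s$times, s$totals)
  expect_equal(jk$n_subsamples, choose(8, 2))
  expect_error(jackknife_ci(1:5, 4 * (0:4), rep(10, 5)), "at least d \\+ 4")
})

test_that("a high-depth series gives a tight jackknife CI around the truth", {
  set.seed(65)
  s <- rhythmic_series(depth = 1e7, rel = 1e-3, amp = 0.5, phase = 15,
                       sigma = 0)
  jk <- jackknife_ci(s$counts, s$times, s$totals)
  expect_lt(jk$ci_width_min, 30)
  expect_lt(circ_diff(jk$t_peak_full, 15), 0.05)
  expect_true(jk$ci_low_h <= jk$t_peak_full && jk$t_peak_full <= jk$ci_high_h)
  expect_equal(jk$n_converged, jk$n_subsamples)
})

test_that("jackknife quantile CI is equivariant under time-origin shifts", {
  set.seed(66)
  s <- rhythmic_series(n = 10, depth = 1e5, amp = 0.6, phase = 8)
  j1 <- jackknife_ci(s$counts, s$times, s$totals)
  j2 <- jackknife_ci(s$counts, s$times + 5, s$totals)
  expect_equal((j2$ci_low_h - j1$ci_low_h) %% 24, 5, tolerance = 1e-6)
  expect_equal((j2$ci_high_h - j1$ci_high_h) %% 24, 5, tolerance = 1e-6)
  expect_equal(j2$ci_width_min, j1$ci_width_min, tolerance = 1e-6)
})

test_that("estimate_peaks returns a tidy table plus subsample peaks", {
  set.seed(67)
  d <- diel_design(24, 4)
  g <- gene_table(2, 0, amplitude_ratio = 0.6, peak_phase_h = c(5, 20))
  sim <- simulate_counts(d, g, 2e4, seed = 68)
  pk <- estimate_peaks(sim$counts, sim$totals, d = 2)
  expect_s3_class(pk, "diel_peaks")
  expect_equal(nrow(pk), 2)
  expect_true(all(pk$converged))
  expect_lt(max(circ_diff(sort(pk$t_peak_h), c(5, 20))), 1.5)
  sp <- subsample_peaks(pk)
  expect_equal(nrow(sp), sum(pk$n_converged))
  pk2 <- estimate_peaks(sim$counts, sim$totals, jackknife = FALSE)
  expect_error(subsample_peaks(pk2), "jackknife")
})

test_that("tidy and glance summarise a harmonic fit", {
  set.seed(69)
  s <- rhythmic_series()
  fit <- fit_harmonic_poisson(s$counts, s$times, s$totals)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "cos", "sin"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 44)
  expect_equal(gl$t_peak_h, fit$t_peak_h)
  jk <- jackknife_ci(s$counts, s$times, s$totals, d = 1)
  expect_equal(tidy(jk)$n_subsamples, 44)
})
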