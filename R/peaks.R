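#' Fit the Poisson log-linear harmonic (cosinor) model to one series
#'
#' Maximum-likelihood fit of
#' `x_t ~ Poisson(N_t * exp(c + alpha * cos(2 pi t / 24) + beta * sin(2 pi t / 24)))`
#' by iteratively reweighted least squares (Fisher scoring). The log library
#' total enters as an offset, so `c` models log relative abundance and
#' `(alpha, beta)` the 24-h harmonic. The fit starts at
#' `c = log(sum(x)/sum(N))`, `alpha = beta = 0`, iterates to a relative
#' deviance change below `tol`, and halves the step when the deviance
#' worsens.
#'
#' @param counts Integer vector of counts `x_t` (at least one nonzero).
#' @param times Sampling times in hours (at least 4 points).
#' @param totals Positive library totals `N_t`.
#' @param period_h Period of the harmonic in hours (default 24).
#' @param tol Relative-deviance convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return An object of class `harmonic_fit`: a list with `coef`
#'   (`c`, `alpha`, `beta`), `amplitude`, `phase_shift_h`, `t_peak_h`,
#'   `deviance`, `null_deviance`, `df_residual`, `converged`, `n_iter`,
#'   and the inputs (`counts`, `times`, `totals`, `period_h`).
#' @examples
#' tm <- seq(0, 172, by = 4)
#' N <- rep(1e4, length(tm))
#' x <- rpois(length(tm), N * 1e-3 * (1 + 0.5 * cos(2 * pi * (tm - 6) / 24)))
#' fit <- fit_harmonic_poisson(x, tm, N)
#' fit$t_peak_h
#' @export
fit_harmonic_poisson <- function(counts, times, totals, period_h = 24,
                                 tol = 1e-10, max_iter = 100) {
  n <- length(counts)
  stopifnot(length(times) == n, length(totals) == n)
  if (n < 4) stop("need at least 4 time points", call. = FALSE)
  if (any(totals <= 0)) stop("all totals must be positive", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * times), sin(w * times))
  off <- log(totals)
  beta_hat <- c(log(sum(counts) / sum(totals)), 0, 0)
  dev <- poisson_deviance(counts, exp(off + X %*% beta_hat))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- off + drop(X %*% beta_hat)
    mu <- exp(eta)
    # Fisher scoring step: weighted least squares on the working response
    z <- (eta - off) + (counts - mu) / mu
    XtW <- t(X * mu)
    step_ok <- FALSE
    delta <- tryCatch(
      solve(XtW %*% X, XtW %*% z) - beta_hat,
      error = function(e) NULL
    )
    if (is.null(delta)) break
    fac <- 1
    for (half in 1:20) {
      cand <- beta_hat + fac * drop(delta)
      mu_new <- exp(off + drop(X %*% cand))
      dev_new <- poisson_deviance(counts, mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) {
        step_ok <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!step_ok) break
    rel <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    beta_hat <- cand
    dev <- dev_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  alpha <- beta_hat[2]
  beta <- beta_hat[3]
  null_dev <- poisson_deviance(counts,
                               exp(off + log(sum(counts) / sum(totals))))
  amp <- sqrt(alpha^2 + beta^2)
  out <- list(
    coef = c(c = beta_hat[1], alpha = alpha, beta = beta),
    amplitude = amp,
    phase_shift_h = (period_h / (2 * pi)) * atan2(beta, alpha),
    t_peak_h = if (amp > 0) peak_time(alpha, beta, period_h) else NA_real_,
    deviance = dev,
    null_deviance = null_dev,
    df_residual = n - 3L,
    converged = converged,
    n_iter = iter,
    counts = counts, times = times, totals = totals, period_h = period_h
  )
  class(out) <- "harmonic_fit"
  out
}

poisson_deviance <- function(x, mu) {
  term <- ifelse(x > 0, x * log(x / mu), 0)
  2 * sum(term - (x - mu))
}

#' Peak time of a fitted 24-h harmonic
#'
#' The fitted log-rate term `alpha * cos(w t) + beta * sin(w t)` (with
#' `w = 2 pi / period`) equals `A * cos(w (t - t_peak))`, so the peak falls
#' at `t_peak = (period / 2 pi) * atan2(beta, alpha)`, reduced to
#' `[0, period)`. The quadrant-safe `atan2` form is used so the peak is
#' correct for all sign combinations of the coefficients.
#'
#' @param alpha,beta Cosine and sine coefficients (not both zero).
#' @param period_h Period in hours (default 24).
#' @return Peak time in hours, in `[0, period_h)`.
#' @examples
#' peak_time(0, 1)   # 6
#' peak_time(1, 0)   # 0
#' peak_time(1, 1)   # 3
#' @export
peak_time <- function(alpha, beta, period_h = 24) {
  if (alpha == 0 && beta == 0) {
    stop("undefined phase: zero amplitude", call. = FALSE)
  }
  ((period_h / (2 * pi)) * atan2(beta, alpha)) %% period_h
}

#' Likelihood-ratio significance of the harmonic fit
#'
#' Compares the harmonic model against the intercept-only model (both with
#' the library-size offset) by the deviance difference, referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param fit A `harmonic_fit` from [fit_harmonic_poisson()].
#' @return The p value.
#' @examples
#' # a deviance drop of 5.991 on 2 df sits at p = 0.05
#' @export
lrt_significance <- function(fit) {
  stats::pchisq(max(fit$null_deviance - fit$deviance, 0), df = 2,
                lower.tail = FALSE)
}

#' Number of delete-d jackknife subsamples
#'
#' The exhaustive delete-d jackknife refits on every subsample obtained by
#' deleting `d` of the `n` time points, so the number of refits is the
#' binomial coefficient `choose(n, d)`: 946 for 44 points with `d = 2`.
#'
#' @param n Number of time points.
#' @param d Number of deleted points.
#' @return `choose(n, d)`.
#' @examples
#' jackknife_subsample_count(44, 2)  # 946
#' @export
jackknife_subsample_count <- function(n, d) {
  stopifnot(n >= d, d >= 1)
  choose(n, d)
}

#' Delete-d jackknife confidence interval for a peak time
#'
#' Enumerates every subsample obtained by deleting `d` of the `n` time
#' points (all `choose(n, d)` of them — for 44 points and `d = 2` that is
#' 946 subsamples), refits the harmonic model on each, and takes quantiles
#' of the subsample peak times as the confidence interval. Subsample peaks
#' are first unwrapped into the half-period window around the full-data
#' peak so the circular quantity is treated on a common linear scale;
#' quantiles use linear interpolation between order statistics (type 7).
#' Degenerate subsamples (all counts zero) and non-converged refits are
#' dropped from the quantile set and reported via `n_converged`; a warning
#' is raised when more than 5% drop out.
#'
#' @inheritParams fit_harmonic_poisson
#' @param d Number of deleted time points (default 2).
#' @param coverage Central coverage of the interval (default 0.90: the 5%
#'   and 95% quantiles).
#' @return An object of class `diel_jackknife`: a list with `t_peak_full`,
#'   `subsample_peaks` (unwrapped, converged refits only), `ci_low_h`,
#'   `ci_high_h`, `ci_width_min`, `n_subsamples`, `n_converged`.
#' @export
jackknife_ci <- function(counts, times, totals, d = 2, coverage = 0.90,
                         period_h = 24) {
  n <- length(counts)
  if (n < d + 4) stop("need at least d + 4 time points", call. = FALSE)
  full <- fit_harmonic_poisson(counts, times, totals, period_h)
  t_full <- full$t_peak_h
  drops <- utils::combn(n, d)
  peaks <- apply(drops, 2, function(ix) {
    x <- counts[-ix]
    if (all(x == 0)) return(NA_real_)
    f <- tryCatch(
      fit_harmonic_poisson(x, times[-ix], totals[-ix], period_h),
      error = function(e) NULL
    )
    if (is.null(f) || !f$converged || f$amplitude == 0) NA_real_ else f$t_peak_h
  })
  ok <- !is.na(peaks)
  if (!any(ok)) stop("no jackknife subsample converged", call. = FALSE)
  if (mean(ok) < 0.95) {
    warning(sprintf("only %d of %d jackknife refits converged",
                    sum(ok), ncol(drops)))
  }
  # unwrap each subsample peak into (t_full - period/2, t_full + period/2]
  unwrapped <- t_full +
    ((peaks[ok] - t_full + period_h / 2) %% period_h) - period_h / 2
  qs <- stats::quantile(unwrapped, c((1 - coverage) / 2, (1 + coverage) / 2),
                        type = 7, names = FALSE)
  out <- list(
    t_peak_full = t_full,
    subsample_peaks = unwrapped,
    ci_low_h = qs[1],
    ci_high_h = qs[2],
    ci_width_min = 60 * (qs[2] - qs[1]),
    n_subsamples = ncol(drops),
    n_converged = sum(ok)
  )
  class(out) <- "diel_jackknife"
  out
}

#' Estimate peak expression times for periodic genes
#'
#' Tidy front end to peak estimation: for each (periodic) unit, fits the
#' Poisson harmonic model with library-size offset, computes amplitude,
#' peak time and the chi-squared significance of fit (BH-adjusted across
#' units), and — optionally — the delete-d jackknife confidence interval of
#' the peak time.
#'
#' @inheritParams detect_rhythms
#' @param rhythm Optional `diel_rhythm` tibble from [detect_rhythms()]; when
#'   given, only units with `periodic == TRUE` are fitted.
#' @param jackknife Compute jackknife CIs (default `TRUE`; the dominant
#'   cost, `choose(n, d)` refits per unit).
#' @param d,coverage Passed to [jackknife_ci()].
#' @param fdr Threshold on the BH-adjusted fit p value flagged in
#'   `fit_significant`.
#' @return A tibble of class `diel_peaks` with one row per unit: `unit_id`,
#'   `alpha`, `beta`, `amplitude`, `t_peak_h`, `lrt_p`, `lrt_p_fdr`,
#'   `fit_significant`, `converged`, and (with `jackknife = TRUE`)
#'   `ci_low_h`, `ci_high_h`, `ci_width_min`, `n_converged`. The per-unit
#'   subsample peaks are kept in the `subsample_peaks` attribute (a long
#'   tibble `unit_id`, `peak_h`) for violin-style plots.
#' @examples
#' sim <- simulate_counts(diel_design(24, 4), gene_table(2, 0), 5e3, seed = 2)
#' pk <- estimate_peaks(sim$counts, sim$totals, jackknife = FALSE)
#' pk$t_peak_h
#' @export
estimate_peaks <- function(counts, totals, rhythm = NULL, period_h = 24,
                           jackknife = TRUE, d = 2, coverage = 0.90,
                           fdr = 0.1) {
  counts <- normalize_id(counts)
  if (!is.null(rhythm)) {
    keep <- rhythm$unit_id[rhythm$periodic]
    counts <- dplyr::filter(counts, .data$unit_id %in% keep)
  }
  if (nrow(counts) == 0) stop("no units to fit", call. = FALSE)
  joined <- dplyr::left_join(counts, totals, by = "sample") |>
    dplyr::arrange(.data$unit_id, .data$time_h)
  units <- split(joined, joined$unit_id)
  rows <- purrr::map(units, function(df) {
    fit <- fit_harmonic_poisson(df$count, df$time_h, df$total, period_h)
    row <- tibble::tibble(
      unit_id = df$unit_id[1],
      alpha = fit$coef[["alpha"]],
      beta = fit$coef[["beta"]],
      amplitude = fit$amplitude,
      t_peak_h = fit$t_peak_h,
      lrt_p = lrt_significance(fit),
      converged = fit$converged
    )
    if (jackknife) {
      jk <- jackknife_ci(df$count, df$time_h, df$total, d, coverage, period_h)
      row$ci_low_h <- jk$ci_low_h
      row$ci_high_h <- jk$ci_high_h
      row$ci_width_min <- jk$ci_width_min
      row$n_converged <- jk$n_converged
      attr(row, "peaks") <- tibble::tibble(unit_id = df$unit_id[1],
                                           peak_h = jk$subsample_peaks)
    }
    row
  })
  res <- dplyr::bind_rows(rows)
  res$lrt_p_fdr <- fdr_bh(res$lrt_p)
  res$fit_significant <- res$lrt_p_fdr < fdr
  res <- dplyr::relocate(res, "lrt_p_fdr", "fit_significant",
                         .after = "lrt_p")
  if (jackknife) {
    attr(res, "subsample_peaks") <-
      dplyr::bind_rows(purrr::map(rows, ~ attr(.x, "peaks")))
  }
  class(res) <- c("diel_peaks", class(res))
  res
}

#' Subsample peak times from a `diel_peaks` table
#'
#' @param peaks A `diel_peaks` tibble from [estimate_peaks()] run with
#'   `jackknife = TRUE`.
#' @return Long tibble `unit_id`, `peak_h` of jackknife subsample peaks.
#' @export
subsample_peaks <- function(peaks) {
  sp <- attr(peaks, "subsample_peaks")
  if (is.null(sp)) stop("no jackknife peaks stored; rerun with jackknife = TRUE",
                        call. = FALSE)
  sp
}
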