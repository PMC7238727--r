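#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a harmonic fit
#'
#' @param x A `harmonic_fit` from [fit_harmonic_poisson()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`).
#' @export
tidy.harmonic_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "cos", "sin"),
                 estimate = unname(x$coef))
}

#' One-row summary of a harmonic fit
#'
#' @inheritParams tidy.harmonic_fit
#' @return A tibble with `amplitude`, `phase_shift_h`, `t_peak_h`,
#'   `deviance`, `null_deviance`, `df_residual`, `lrt_p`, `converged`,
#'   `nobs`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude,
    phase_shift_h = x$phase_shift_h,
    t_peak_h = x$t_peak_h,
    deviance = x$deviance,
    null_deviance = x$null_deviance,
    df_residual = x$df_residual,
    lrt_p = lrt_significance(x),
    converged = x$converged,
    nobs = length(x$counts)
  )
}

#' Tidy a jackknife result
#'
#' @param x A `diel_jackknife` from [jackknife_ci()].
#' @param ... Unused.
#' @return A one-row tibble with the point estimate, CI bounds, CI width in
#'   minutes, and subsample bookkeeping.
#' @export
tidy.diel_jackknife <- function(x, ...) {
  tibble::tibble(
    t_peak_h = x$t_peak_full,
    ci_low_h = x$ci_low_h,
    ci_high_h = x$ci_high_h,
    ci_width_min = x$ci_width_min,
    n_subsamples = x$n_subsamples,
    n_converged = x$n_converged
  )
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Poisson harmonic fit (period", x$period_h, "h)\n")
  cat(sprintf("  c = %.4f, alpha = %.4f, beta = %.4f\n",
              x$coef[1], x$coef[2], x$coef[3]))
  cat(sprintf("  amplitude = %.4f, t_peak = %.2f h, converged: %s\n",
              x$amplitude, x$t_peak_h, x$converged))
  invisible(x)
}

#' @export
print.diel_jackknife <- function(x, ...) {
  cat(sprintf("Delete-d jackknife: t_peak = %.2f h, %d%% of %d refits converged\n",
              x$t_peak_full, round(100 * x$n_converged / x$n_subsamples),
              x$n_subsamples))
  cat(sprintf("  CI [%.2f, %.2f] h (width %.0f min)\n",
              x$ci_low_h, x$ci_high_h, x$ci_width_min))
  invisible(x)
}
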