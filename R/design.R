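#' Diel sampling design
#'
#' Builds the sampling design for a multi-day diel time series: sample labels,
#' sampling times in hours since local midnight of day 1, and the night
#' windows (sunset to sunrise) used to annotate plots. The default reproduces
#' a field design of 44 samples taken every 4 hours over 8 days.
#'
#' @param n_points Number of sampling time points (at least 3).
#' @param interval_h Spacing between consecutive samples, in hours. Must be
#'   positive.
#' @param start_h Clock time of the first sample, in hours since local
#'   midnight of day 1.
#' @param times Optional explicit vector of sampling times (hours, strictly
#'   increasing). Overrides `n_points`/`interval_h`/`start_h`; use it when
#'   the series has gaps.
#' @param sunset_h,sunrise_h Local sunset and sunrise clock times in hours,
#'   used only to annotate night periods. The default sunset of 19.183 h is
#'   19:11 local time.
#'
#' @return A tibble of class `diel_design` with columns `sample`, `time_h`,
#'   `day` (1-based day index), `clock_h` (time of day in `[0, 24)`) and
#'   `is_night`. The night windows are stored in the `night_windows`
#'   attribute as a tibble with columns `night_start_h`, `night_end_h` in
#'   absolute hours.
#'
#' @examples
#' d <- diel_design()
#' nrow(d)              # 44
#' max(d$time_h)        # 172 when start_h = 0
#' @export
diel_design <- function(n_points = 44, interval_h = 4, start_h = 0,
                        times = NULL, sunset_h = 19.183, sunrise_h = 6.0) {
  if (is.null(times)) {
    if (n_points < 3) stop("`n_points` must be at least 3", call. = FALSE)
    if (interval_h <= 0) stop("`interval_h` must be positive", call. = FALSE)
    times <- start_h + interval_h * (seq_len(n_points) - 1)
  } else {
    times <- as.numeric(times)
    if (length(times) < 3) stop("need at least 3 sampling times", call. = FALSE)
    if (any(!is.finite(times)) || any(times < 0)) {
      stop("sampling times must be finite and non-negative", call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("sampling times must be strictly increasing", call. = FALSE)
    }
  }
  clock <- times %% 24
  # night runs from sunset to next sunrise
  is_night <- clock >= sunset_h | clock < sunrise_h
  out <- tibble::tibble(
    sample = sprintf("S%03d", seq_along(times)),
    time_h = times,
    day = floor(times / 24) + 1L,
    clock_h = clock,
    is_night = is_night
  )
  n_days <- ceiling((max(times) + 1e-9) / 24)
  attr(out, "night_windows") <- tibble::tibble(
    night_start_h = sunset_h + 24 * (seq_len(n_days) - 1),
    night_end_h = sunrise_h + 24 * seq_len(n_days)
  )
  attr(out, "sunset_h") <- sunset_h
  attr(out, "sunrise_h") <- sunrise_h
  class(out) <- c("diel_design", class(out))
  out
}

#' Night windows of a sampling design
#'
#' @param design A `diel_design` tibble from [diel_design()].
#' @return A tibble with one row per night (`night_start_h`, `night_end_h`
#'   in absolute hours since midnight of day 1).
#' @export
night_windows <- function(design) {
  nw <- attr(design, "night_windows")
  if (is.null(nw)) stop("`design` carries no night windows", call. = FALSE)
  nw
}
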