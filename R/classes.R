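#' Assign periodic orthologs to early/middle/late classes
#'
#' Joins estimated peak times against a curated class annotation (derived
#' from synchronized-infection time courses of cultured phages). Orthologs
#' without an annotation are reported as `"unclassified"`; an ortholog
#' annotated with two classes is an invalid annotation and errors.
#'
#' @param peaks A `diel_peaks` tibble from [estimate_peaks()] (restricted
#'   to periodic units by construction when a rhythm table was supplied).
#' @param annotation Tibble with columns `ortholog_id` and `temporal_class`
#'   (values among `"early"`, `"middle"`, `"late"`).
#' @return A tibble of class `diel_classes` with columns `unit_id`,
#'   `temporal_class`, `t_peak_h`.
#' @examples
#' pk <- tibble::tibble(unit_id = c("OG1", "OG2"), t_peak_h = c(10, 21))
#' ann <- tibble::tibble(ortholog_id = "OG2", temporal_class = "late")
#' classify_peaks(pk, ann)
#' @export
classify_peaks <- function(peaks, annotation) {
  if (anyDuplicated(annotation$ortholog_id) > 0) {
    dup <- annotation$ortholog_id[duplicated(annotation$ortholog_id)]
    stop("ortholog annotated with more than one class: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(annotation$temporal_class),
                 c("early", "middle", "late"))
  if (length(bad) > 0) {
    stop("unknown temporal class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- peaks |>
    dplyr::left_join(
      dplyr::rename(annotation, unit_id = "ortholog_id"),
      by = "unit_id"
    ) |>
    dplyr::mutate(temporal_class = dplyr::coalesce(.data$temporal_class,
                                                   "unclassified")) |>
    dplyr::select("unit_id", "temporal_class", "t_peak_h")
  class(out) <- c("diel_classes", class(out))
  out
}

#' Two-sample comparison of peak-time classes
#'
#' Classic two-tailed Student's t test (pooled variance by default, Welch
#' optional) between two sets of peak times. Peak times should first be
#' unwrapped onto a linear scale (see [anchor_times()]); the test itself is
#' location/scale equivariant, so any common anchor gives the same result.
#'
#' @param times_a,times_b Numeric vectors of peak times (hours), each of
#'   length at least 2.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return A one-row tibble: `n_a`, `n_b`, `t_statistic`, `df`, `p`,
#'   `significant` (`p < 0.05`).
#' @examples
#' compare_classes(c(9, 10, 9.5), c(20, 21, 22))
#' @export
compare_classes <- function(times_a, times_b, welch = FALSE) {
  if (length(times_a) < 2 || length(times_b) < 2) {
    stop("each class needs at least 2 peak times", call. = FALSE)
  }
  if (stats::var(times_a) == 0 && stats::var(times_b) == 0) {
    if (mean(times_a) == mean(times_b)) {
      return(tibble::tibble(n_a = length(times_a), n_b = length(times_b),
                            t_statistic = 0,
                            df = length(times_a) + length(times_b) - 2,
                            p = 1, significant = FALSE))
    }
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(times_a, times_b, var.equal = !welch)
  tibble::tibble(
    n_a = length(times_a), n_b = length(times_b),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    significant = tt$p.value < 0.05
  )
}

#' Unwrap clock-circular peak times onto a linear scale
#'
#' Peak times live on a 24-h circle; before a linear two-sample test they
#' are re-expressed as hours since a fixed anchor (dawn, 06:00, by
#' default), i.e. `(t - anchor) mod 24`. With all observed peaks inside one
#' diel cycle this is a plain rotation and leaves within-cycle differences
#' intact.
#'
#' @param t_peak_h Peak times in hours.
#' @param anchor_h Anchor clock time in hours (default 6).
#' @return Hours since the anchor, in `[0, 24)`.
#' @export
anchor_times <- function(t_peak_h, anchor_h = 6) {
  (t_peak_h - anchor_h) %% 24
}

#' All pairwise class comparisons of peak times
#'
#' Runs [compare_classes()] for every pair of annotated classes after
#' anchoring the peak times with [anchor_times()]. Unclassified units are
#' excluded.
#'
#' @param classified A `diel_classes` tibble from [classify_peaks()].
#' @param anchor_h Anchor for the linearization (default 6, dawn).
#' @param welch Use Welch's variant.
#' @return A tibble with one row per class pair: `class_a`, `class_b`,
#'   `n_a`, `n_b`, `t_statistic`, `df`, `p`, `significant`.
#' @export
compare_all_classes <- function(classified, anchor_h = 6, welch = FALSE) {
  cl <- dplyr::filter(classified, .data$temporal_class != "unclassified")
  lv <- intersect(c("early", "middle", "late"),
                  unique(cl$temporal_class))
  if (length(lv) < 2) stop("need at least two annotated classes", call. = FALSE)
  prs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(prs, function(pr) {
    a <- anchor_times(cl$t_peak_h[cl$temporal_class == pr[1]], anchor_h)
    b <- anchor_times(cl$t_peak_h[cl$temporal_class == pr[2]], anchor_h)
    dplyr::bind_cols(tibble::tibble(class_a = pr[1], class_b = pr[2]),
                     compare_classes(a, b, welch))
  })
}
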