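#' Run the full diel-rhythm pipeline
#'
#' Composes the stages end to end: read assignment (score filter, ambiguity
#' rules, ortholog binning, tabulation), the 24-h periodicity screen with
#' FDR control, harmonic peak-time estimation with jackknife confidence
#' intervals for the periodic units, and — when a class annotation is given
#' — early/middle/late classification and pairwise class comparisons. The
#' pipeline is a pure function of its inputs and parameters: identical
#' reruns give identical outputs.
#'
#' @param hits Read-level alignment-hit tibble (see [assign_reads()]).
#' @param ortholog_map Optional gene-to-ortholog map tibble.
#' @param annotation Optional early/middle/late annotation tibble
#'   (`ortholog_id`, `temporal_class`).
#' @param design Optional [diel_design()]; improvised from the hits when
#'   absent.
#' @param cutoff Bit-score cutoff (default 50).
#' @param period_h,interval_h Rhythm period and phase-group width in hours.
#' @param fdr FDR threshold for periodicity and fit significance
#'   (default 0.1).
#' @param min_total Eligibility threshold; defaults to the number of time
#'   points.
#' @param jackknife,d,coverage Jackknife controls (see [jackknife_ci()]).
#' @param anchor_h Linearization anchor for class comparisons.
#' @param welch Use Welch's t variant in class comparisons.
#' @return A list of class `diel_pipeline` with elements `assignment`,
#'   `rhythm`, `peaks`, `classes` (or `NULL`), `comparisons` (or `NULL`),
#'   `group_summary` and `log` (per-stage record counts).
#' @examples
#' sim <- simulate_counts(diel_design(24, 4), gene_table(3, 2), 2e3, seed = 1)
#' res <- run_pipeline(sim_to_hits(sim), jackknife = FALSE)
#' res$log
#' @export
run_pipeline <- function(hits, ortholog_map = NULL, annotation = NULL,
                         design = NULL, cutoff = 50, period_h = 24,
                         interval_h = 4, fdr = 0.1, min_total = NULL,
                         jackknife = TRUE, d = 2, coverage = 0.90,
                         anchor_h = 6, welch = FALSE) {
  if (is.null(hits) || nrow(hits) == 0) {
    stop("assign stage: empty hit table", call. = FALSE)
  }
  asg <- with_stage("assign",
                    assign_reads(hits, ortholog_map, cutoff, design))
  rhy <- with_stage("rhythm",
                    detect_rhythms(asg$counts, asg$totals, period_h,
                                   interval_h, min_total, fdr))
  pk <- if (any(rhy$periodic)) {
    with_stage("peaks",
               estimate_peaks(asg$counts, asg$totals, rhythm = rhy,
                              period_h = period_h, jackknife = jackknife,
                              d = d, coverage = coverage, fdr = fdr))
  } else {
    NULL
  }
  cls <- cmp <- NULL
  if (!is.null(annotation) && !is.null(pk)) {
    cls <- with_stage("classify", classify_peaks(pk, annotation))
    n_cl <- table(cls$temporal_class[cls$temporal_class != "unclassified"])
    if (sum(n_cl >= 2) >= 2) {
      cmp <- with_stage("compare",
                        compare_all_classes(cls, anchor_h, welch))
    }
  }
  grp <- summarize_groups(rhy)
  log <- tibble::tibble(
    stage = c("input_reads", "assigned_reads", "discarded_reads",
              "units_tested", "units_eligible", "units_periodic",
              "units_fit", "units_classified"),
    n = c(asg$n_input,
          asg$n_input - nrow(asg$discards),
          nrow(asg$discards),
          nrow(rhy),
          sum(rhy$eligible),
          sum(rhy$periodic),
          if (is.null(pk)) 0L else nrow(pk),
          if (is.null(cls)) 0L else sum(cls$temporal_class != "unclassified"))
  )
  out <- list(assignment = asg, rhythm = rhy, peaks = pk, classes = cls,
              comparisons = cmp, group_summary = grp, log = log)
  class(out) <- "diel_pipeline"
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Per-group tally of tested and periodic units
#'
#' Counts, for each virus group, how many units were tested and how many
#' were called periodic, with the periodic fraction.
#'
#' @param rhythm A `diel_rhythm` tibble from [detect_rhythms()] carrying a
#'   `group` column (present when the counts came from [assign_reads()]).
#' @param groups Optional tibble `unit_id`, `group` supplying labels when
#'   the rhythm table has none.
#' @return A tibble `group`, `n_total`, `n_periodic`, `fraction_periodic`.
#' @export
summarize_groups <- function(rhythm, groups = NULL) {
  if (!"group" %in% names(rhythm)) {
    if (is.null(groups)) {
      rhythm$group <- "all"
    } else {
      rhythm <- dplyr::left_join(rhythm, groups, by = "unit_id")
      if (any(is.na(rhythm$group))) {
        stop("every unit needs a group label", call. = FALSE)
      }
    }
  }
  rhythm |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_periodic = sum(.data$periodic),
      fraction_periodic = ifelse(dplyr::n() > 0,
                                 sum(.data$periodic) / dplyr::n(), 0),
      .groups = "drop"
    )
}

#' @export
print.diel_pipeline <- function(x, ...) {
  cat("Diel rhythm pipeline\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-18s %d\n", x$log$stage[i], x$log$n[i]))
  }
  invisible(x)
}
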