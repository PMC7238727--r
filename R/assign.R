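#' Filter alignment hits by bit score
#'
#' Keeps hits whose bit score is at or above the cutoff. The cutoff is
#' inclusive: a hit scoring exactly the cutoff survives.
#'
#' @param hits A tibble of alignment hits with at least a `bit_score`
#'   column (one row per read-subject pair).
#' @param cutoff Bit-score cutoff (default 50).
#' @return The filtered tibble.
#' @examples
#' h <- tibble::tibble(read_id = c("r1", "r2"), bit_score = c(49, 50))
#' filter_by_score(h)$read_id
#' @export
filter_by_score <- function(hits, cutoff = 50) {
  if (cutoff < 0) stop("`cutoff` must be non-negative", call. = FALSE)
  if (any(!is.finite(hits$bit_score))) {
    stop("bit scores must be finite", call. = FALSE)
  }
  dplyr::filter(hits, .data$bit_score >= cutoff)
}

#' Resolve each read to its best-hit gene or discard it
#'
#' Applies the ambiguity rules to score-filtered hits, read by read. Among a
#' read's hits, the genes attaining the maximum bit score are found
#' ("aligned equally well" means exact score equality). The read is
#' discarded when that maximal set spans more than one virus group
#' (`multi_group_tie`) or contains both a virus and a non-virus subject
#' (`virus_host_tie`). Equally-best hits to several genes of a single virus
#' group are carried forward and resolved at ortholog binning.
#'
#' @param hits A tibble of score-filtered hits with columns `read_id`,
#'   `sample`, `time_h`, `gene_id`, `group`, `is_virus`, `bit_score`.
#' @return A list with `assigned` (tibble: `read_id`, `sample`, `time_h`,
#'   `group`, `is_virus`, and a list-column `gene_ids` of the equally-best
#'   genes) and `discarded` (tibble: `read_id`, `sample`, `reason`).
#' @export
assign_best_hits <- function(hits) {
  if (nrow(hits) == 0) stop("no hits to assign", call. = FALSE)
  best <- hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$bit_score == max(.data$bit_score)) |>
    dplyr::summarise(
      sample = .data$sample[1],
      time_h = .data$time_h[1],
      gene_ids = list(unique(.data$gene_id)),
      n_groups = dplyr::n_distinct(.data$group),
      group = .data$group[1],
      any_virus = any(.data$is_virus),
      any_host = any(!.data$is_virus),
      .groups = "drop"
    )
  reason <- dplyr::case_when(
    best$any_virus & best$any_host ~ "virus_host_tie",
    best$n_groups > 1 ~ "multi_group_tie",
    TRUE ~ NA_character_
  )
  list(
    assigned = best[is.na(reason),
                    c("read_id", "sample", "time_h", "group", "any_virus",
                      "gene_ids")] |>
      dplyr::rename(is_virus = "any_virus"),
    discarded = tibble::tibble(read_id = best$read_id[!is.na(reason)],
                               sample = best$sample[!is.na(reason)],
                               reason = reason[!is.na(reason)])
  )
}

#' Bin assigned reads into orthologs
#'
#' Collapses each read's equally-best gene set to a single counting unit.
#' For genes present in the ortholog map, the read is counted once for the
#' unique ortholog of its best-hit genes; reads whose equally-best genes
#' fall in more than one ortholog are discarded (`multi_ortholog`). Genes
#' absent from the map (e.g. viruses for which no ortholog catalogue
#' exists, or host taxa) bypass binning and are counted under their own
#' gene id; a read tied between several unmapped genes is likewise
#' discarded as `multi_ortholog` since it cannot be counted once.
#'
#' @param assigned The `assigned` tibble from [assign_best_hits()].
#' @param ortholog_map A tibble with columns `gene_id`, `ortholog_id`
#'   (many genes to one ortholog), or `NULL` to skip binning entirely.
#' @return A list with `assigned` (tibble: `read_id`, `sample`, `time_h`,
#'   `group`, `is_virus`, `unit_id` — the ortholog or gene the read counts
#'   for) and `discarded` (`read_id`, `sample`, `reason`).
#' @export
bin_orthologs <- function(assigned, ortholog_map = NULL) {
  if (!is.null(ortholog_map)) {
    if (anyDuplicated(ortholog_map$gene_id) > 0) {
      stop("`ortholog_map` maps some gene to more than one ortholog",
           call. = FALSE)
    }
    lookup <- stats::setNames(ortholog_map$ortholog_id, ortholog_map$gene_id)
  } else {
    lookup <- character()
  }
  units <- purrr::map_chr(assigned$gene_ids, function(gs) {
    mapped <- ifelse(gs %in% names(lookup), unname(lookup[gs]), gs)
    u <- unique(mapped)
    if (length(u) == 1) u else NA_character_
  })
  keep <- !is.na(units)
  out <- assigned[keep, c("read_id", "sample", "time_h", "group", "is_virus")]
  out$unit_id <- units[keep]
  list(
    assigned = out,
    discarded = tibble::tibble(read_id = assigned$read_id[!keep],
                               sample = assigned$sample[!keep],
                               reason = "multi_ortholog")
  )
}

#' Tabulate assigned reads into a count matrix and library totals
#'
#' Builds the per-unit, per-sample integer count table and the per-sample
#' normalization denominators `N_t`: the number of reads, across all taxa,
#' that survived the score filter and ambiguity rules in that sample.
#' Samples with no reads are retained as explicit zeros.
#'
#' @param assigned The `assigned` tibble from [bin_orthologs()].
#' @param design A [diel_design()] tibble; every read's `sample` must occur
#'   in it.
#' @param viral_only Count only viral units in the count table (totals
#'   always include every assigned read). Default `TRUE`.
#' @return A list with `counts` (long tibble: `unit_id`, `group`, `sample`,
#'   `count`) and `totals` (`sample`, `time_h`, `total`).
#' @export
tabulate_assignments <- function(assigned, design, viral_only = TRUE) {
  bad <- setdiff(unique(assigned$sample), design$sample)
  if (length(bad) > 0) {
    stop("sample label(s) not in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  totals <- assigned |>
    dplyr::count(sample = factor(.data$sample, levels = design$sample),
                 .drop = FALSE, name = "total") |>
    dplyr::mutate(sample = as.character(.data$sample),
                  time_h = design$time_h[match(.data$sample, design$sample)]) |>
    dplyr::select("sample", "time_h", "total")
  tab <- if (viral_only) dplyr::filter(assigned, .data$is_virus) else assigned
  counts <- tab |>
    dplyr::count(.data$unit_id, .data$group, .data$sample, name = "count") |>
    tidyr::complete(tidyr::nesting(unit_id, group),
                    sample = design$sample,
                    fill = list(count = 0L)) |>
    dplyr::arrange(.data$unit_id, match(.data$sample, design$sample))
  list(counts = tibble::as_tibble(counts), totals = totals)
}

#' Assign reads end to end: score filter, ambiguity rules, ortholog binning
#'
#' Runs [filter_by_score()], [assign_best_hits()], [bin_orthologs()] and
#' [tabulate_assignments()] in sequence and keeps a per-read disposition
#' log. Every input read appears exactly once in the counts or the discard
#' log.
#'
#' @inheritParams filter_by_score
#' @inheritParams bin_orthologs
#' @inheritParams tabulate_assignments
#' @param design A [diel_design()] tibble; if `NULL`, one is improvised
#'   from the distinct (`sample`, `time_h`) pairs present in `hits`.
#' @return A list of class `diel_assignment` with `counts`, `totals`,
#'   `discards` (tibble: `read_id`, `sample`, `reason` in `low_score`,
#'   `virus_host_tie`, `multi_group_tie`, `multi_ortholog`) and `n_input`
#'   (number of distinct input reads).
#' @examples
#' hs <- simulate_hits(diel_design(4, 4), gene_table(2, 0), seed = 1,
#'                     reads_per_sample = 30)
#' asg <- assign_reads(hs$hits, hs$ortholog_map)
#' dplyr::count(asg$discards, reason)
#' @export
assign_reads <- function(hits, ortholog_map = NULL, cutoff = 50,
                         design = NULL, viral_only = TRUE) {
  if (nrow(hits) == 0) stop("empty hit table", call. = FALSE)
  if (is.null(design)) {
    st <- dplyr::distinct(hits[, c("sample", "time_h")]) |>
      dplyr::arrange(.data$time_h)
    design <- tibble::tibble(sample = st$sample, time_h = st$time_h)
  }
  read_sample <- dplyr::distinct(hits[, c("read_id", "sample")])
  kept_score <- filter_by_score(hits, cutoff)
  low <- dplyr::anti_join(read_sample,
                          dplyr::distinct(kept_score[, "read_id"]),
                          by = "read_id")
  if (nrow(kept_score) > 0) {
    step2 <- assign_best_hits(kept_score)
    step3 <- bin_orthologs(step2$assigned, ortholog_map)
  } else {
    empty <- tibble::tibble(read_id = character(), sample = character(),
                            reason = character())
    step2 <- list(discarded = empty)
    step3 <- list(assigned = tibble::tibble(read_id = character(),
                                            sample = character(),
                                            time_h = numeric(),
                                            group = character(),
                                            is_virus = logical(),
                                            unit_id = character()),
                  discarded = empty)
  }
  discards <- dplyr::bind_rows(
    tibble::tibble(read_id = low$read_id, sample = low$sample,
                   reason = "low_score"),
    step2$discarded,
    step3$discarded
  )
  tabs <- tabulate_assignments(step3$assigned, design, viral_only)
  out <- c(tabs, list(discards = discards,
                      n_input = nrow(read_sample),
                      design = design))
  class(out) <- "diel_assignment"
  out
}
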