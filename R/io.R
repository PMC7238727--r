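#' Read an alignment hit table from TSV
#'
#' Accepts either the native format — a header row with columns `read_id`,
#' `sample`, `time_h`, `gene_id`, `group`, `is_virus`, `bit_score` — or a
#' headerless 14-column BLAST-tabular dialect (the standard 12 outfmt-6
#' columns plus `sample` and `time_h`), in which case column 1 is the read,
#' column 2 the subject gene, column 12 the bit score, and a `gene_info`
#' table must supply each gene's `group` and `is_virus` flag.
#'
#' @param path Path to the TSV file.
#' @param gene_info Tibble `gene_id`, `group`, `is_virus`; required for the
#'   BLAST dialect, ignored otherwise.
#' @return A hits tibble suitable for [assign_reads()].
#' @export
read_hits_tsv <- function(path, gene_info = NULL) {
  head1 <- readr::read_lines(path, n_max = 1)
  if (grepl("\\bread_id\\b", head1)) {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("read_id", "sample", "time_h", "gene_id", "group",
              "is_virus", "bit_score")
    missing_cols <- setdiff(need, names(out))
    if (length(missing_cols) > 0) {
      stop("hit table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    return(out[, need])
  }
  blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore", "sample", "time_h")
  raw <- readr::read_tsv(path, col_names = blast_cols, show_col_types = FALSE)
  if (is.null(gene_info)) {
    stop("BLAST-tabular input needs a `gene_info` table (gene_id, group, is_virus)",
         call. = FALSE)
  }
  out <- tibble::tibble(
    read_id = raw$qseqid,
    sample = raw$sample,
    time_h = raw$time_h,
    gene_id = raw$sseqid,
    bit_score = raw$bitscore
  )
  out <- dplyr::left_join(out, gene_info, by = "gene_id")
  if (any(is.na(out$group)) || any(is.na(out$is_virus))) {
    stop("`gene_info` does not cover every subject gene", call. = FALSE)
  }
  out[, c("read_id", "sample", "time_h", "gene_id", "group", "is_virus",
          "bit_score")]
}

#' Read a gene-to-ortholog map from TSV
#'
#' @param path TSV with columns `gene_id`, `ortholog_id`.
#' @return A tibble.
#' @export
read_ortholog_map_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "ortholog_id") %in% names(out))) {
    stop("ortholog map needs columns gene_id, ortholog_id", call. = FALSE)
  }
  out
}

#' Read an early/middle/late class annotation from TSV
#'
#' @param path TSV with columns `ortholog_id`, `temporal_class` (values
#'   `early`/`middle`/`late`); extra columns such as a provenance note are
#'   carried through.
#' @return A tibble.
#' @export
read_annotation_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("ortholog_id", "temporal_class") %in% names(out))) {
    stop("annotation needs columns ortholog_id, temporal_class",
         call. = FALSE)
  }
  out
}

#' Write pipeline results to TSV files
#'
#' Writes one tab-separated file per stage present in a pipeline result:
#' `counts.tsv`, `totals.tsv`, `discards.tsv`, `rhythm.tsv`, `peaks.tsv`,
#' `subsample_peaks.tsv`, `classes.tsv`, `comparisons.tsv`,
#' `group_summary.tsv`, `log.tsv`.
#'
#' @param result A `diel_pipeline` list from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_pipeline_tsv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) readr::write_tsv(df, file.path(dir, name))
  }
  wr(result$assignment$counts, "counts.tsv")
  wr(result$assignment$totals, "totals.tsv")
  wr(result$assignment$discards, "discards.tsv")
  wr(result$rhythm, "rhythm.tsv")
  wr(result$peaks, "peaks.tsv")
  if (!is.null(result$peaks)) {
    sp <- attr(result$peaks, "subsample_peaks")
    wr(sp, "subsample_peaks.tsv")
  }
  wr(result$classes, "classes.tsv")
  wr(result$comparisons, "comparisons.tsv")
  wr(result$group_summary, "group_summary.tsv")
  wr(result$log, "log.tsv")
  invisible(dir)
}
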