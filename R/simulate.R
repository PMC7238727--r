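#' Build a table of synthetic gene specifications
#'
#' Convenience constructor for the gene table consumed by
#' [simulate_counts()] and [simulate_hits()]. Rhythmic genes get peak phases
#' spread evenly over the 24-h cycle (or as supplied); non-rhythmic genes get
#' amplitude 0.
#'
#' @param n_rhythmic,n_null Numbers of rhythmic and arrhythmic genes.
#' @param base_rel_abundance Expected fraction of the library contributed by
#'   each gene at its mesor (recycled across genes).
#' @param amplitude_ratio Relative amplitude `a` in `[0, 1)` of the rhythmic
#'   genes: the Poisson rate is proportional to `1 + a cos(2 pi (t - phi)/24)`.
#' @param peak_phase_h Peak phases (hours in `[0, 24)`) for the rhythmic
#'   genes; defaults to an even spread.
#' @param group Virus-group label (recycled).
#' @param temporal_class Temporal class labels for rhythmic genes
#'   (`"early"`, `"middle"`, `"late"` or `"none"`; recycled).
#'
#' @return A tibble with columns `gene_id`, `group`, `temporal_class`,
#'   `base_rel_abundance`, `amplitude_ratio`, `peak_phase_h`, `rhythmic`.
#' @examples
#' gene_table(3, 2)
#' @export
gene_table <- function(n_rhythmic, n_null,
                       base_rel_abundance = 1e-3,
                       amplitude_ratio = 0.5,
                       peak_phase_h = NULL,
                       group = "cyanomyovirus",
                       temporal_class = "none") {
  stopifnot(n_rhythmic >= 0, n_null >= 0, n_rhythmic + n_null > 0)
  if (any(base_rel_abundance <= 0)) {
    stop("`base_rel_abundance` must be positive", call. = FALSE)
  }
  if (any(amplitude_ratio < 0 | amplitude_ratio >= 1)) {
    stop("`amplitude_ratio` must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(peak_phase_h)) {
    peak_phase_h <- if (n_rhythmic > 0) 24 * (seq_len(n_rhythmic) - 1) / n_rhythmic else numeric()
  }
  n <- n_rhythmic + n_null
  tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n)),
    group = rep_len(group, n),
    temporal_class = c(rep_len(temporal_class, n_rhythmic), rep("none", n_null)),
    base_rel_abundance = rep_len(base_rel_abundance, n),
    amplitude_ratio = c(rep_len(amplitude_ratio, n_rhythmic), rep(0, n_null)),
    peak_phase_h = c(rep_len(peak_phase_h, max(n_rhythmic, 0L)), rep(0, n_null)) %% 24,
    rhythmic = rep(c(TRUE, FALSE), c(n_rhythmic, n_null))
  )
}

#' Simulate diel transcript counts with known ground truth
#'
#' Draws per-gene, per-sample transcript counts from a Poisson model whose
#' rate follows a 24-h sinusoid: the count for gene `g` at time `t` is
#' `Poisson(N_t * r_g * (1 + a_g * cos(2 pi (t - phi_g) / 24)))`, where `N_t`
#' is the per-sample library total, `r_g` the gene's baseline relative
#' abundance, `a_g` its relative amplitude and `phi_g` its peak phase.
#' Library totals are drawn log-normally around `depth_per_sample` to
#' exercise the offset term of the downstream regression.
#'
#' @param design A [diel_design()] tibble.
#' @param genes A gene table as from [gene_table()].
#' @param depth_per_sample Expected library total per sample.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @param depth_sigma Log-scale standard deviation of the per-sample totals;
#'   `0` gives constant totals.
#'
#' @return A list of class `diel_sim` with elements `counts` (long tibble:
#'   `gene_id`, `sample`, `count`), `totals` (`sample`, `time_h`, `total`),
#'   `truth` (the gene table plus per-gene ground truth) and `design`.
#' @examples
#' sim <- simulate_counts(diel_design(12, 4), gene_table(2, 1), 1e4, seed = 1)
#' dplyr::count(sim$counts, gene_id, wt = count)
#' @export
simulate_counts <- function(design, genes, depth_per_sample, seed,
                            depth_sigma = 0.2) {
  stopifnot(depth_per_sample > 0)
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)
  if (any(genes$amplitude_ratio >= 1)) {
    stop("`amplitude_ratio` >= 1 would give a negative Poisson mean", call. = FALSE)
  }
  if (any(genes$amplitude_ratio < 0)) {
    stop("`amplitude_ratio` must be non-negative", call. = FALSE)
  }
  times <- design$time_h
  withr_seed(seed, {
    totals <- if (depth_sigma > 0) {
      round(stats::rlnorm(length(times), log(depth_per_sample), depth_sigma))
    } else {
      rep(round(depth_per_sample), length(times))
    }
    totals <- pmax(totals, 1)
    grid <- tidyr::expand_grid(
      genes[, c("gene_id", "base_rel_abundance", "amplitude_ratio", "peak_phase_h")],
      tibble::tibble(sample = design$sample, time_h = times,
                     total = totals)
    )
    mu <- grid$total * grid$base_rel_abundance *
      (1 + grid$amplitude_ratio * cos(2 * pi * (grid$time_h - grid$peak_phase_h) / 24))
    counts <- stats::rpois(nrow(grid), mu)
  })
  out <- list(
    counts = tibble::tibble(gene_id = grid$gene_id, sample = grid$sample,
                            count = counts),
    totals = tibble::tibble(sample = design$sample, time_h = times,
                            total = totals),
    truth = genes,
    design = design
  )
  class(out) <- "diel_sim"
  out
}

# Run `code` under a fixed seed, restoring the caller's RNG state after.
# Keeps simulations reproducible without clobbering the session RNG.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval(substitute(code), envir = parent.frame())
}

#' Simulate a read-level hit table with labelled dispositions
#'
#' Emits alignment-hit rows whose fate under the filtering rules is known by
#' construction, so filter bookkeeping can be checked exactly. Reads are
#' generated in five categories: cleanly assignable (`kept`), below the score
#' cutoff (`low_score`), equally-best hits in two virus groups
#' (`multi_group_tie`), equally-best hits to a virus and a host protein
#' (`virus_host_tie`), and equally-best hits to two genes in different
#' orthologs of one group (`multi_ortholog`). A two-genes-per-ortholog map
#' covering the supplied genes is generated alongside.
#'
#' @param design A [diel_design()] tibble.
#' @param genes A gene table as from [gene_table()].
#' @param seed Integer seed.
#' @param tie_fraction Fraction of reads emitted as ties, split evenly
#'   between the three tie categories.
#' @param subcutoff_fraction Fraction of reads emitted below the score
#'   cutoff.
#' @param reads_per_sample Number of reads emitted per sample.
#' @param host_fraction Fraction of the cleanly assignable reads that hit
#'   host (non-virus) proteins; these contribute to library totals only.
#' @param cutoff Bit-score cutoff the generated scores straddle.
#'
#' @return A list of class `diel_hits_sim` with `hits` (tibble: `read_id`,
#'   `sample`, `time_h`, `gene_id`, `group`, `is_virus`, `bit_score`),
#'   `ortholog_map` (`gene_id`, `ortholog_id`) and `truth` (per-read
#'   `read_id`, `disposition`).
#' @examples
#' hs <- simulate_hits(diel_design(4, 4), gene_table(2, 0), seed = 1,
#'                     tie_fraction = 0.3, subcutoff_fraction = 0.1,
#'                     reads_per_sample = 20)
#' dplyr::count(hs$truth, disposition)
#' @export
simulate_hits <- function(design, genes, seed, tie_fraction = 0.1,
                          subcutoff_fraction = 0.1, reads_per_sample = 100,
                          host_fraction = 0.3, cutoff = 50) {
  stopifnot(tie_fraction >= 0, tie_fraction <= 1,
            subcutoff_fraction >= 0, subcutoff_fraction <= 1,
            tie_fraction + subcutoff_fraction <= 1)
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)

  map <- ortholog_map_for(genes)
  gene_ids <- genes$gene_id
  groups <- stats::setNames(genes$group, genes$gene_id)
  host_genes <- paste0("host", sprintf("%03d", 1:10))

  n_s <- nrow(design)
  n_tie <- round(reads_per_sample * tie_fraction)
  n_low <- round(reads_per_sample * subcutoff_fraction)
  n_keep <- reads_per_sample - n_tie - n_low
  # split ties across the three categories as evenly as possible
  n_mg <- n_tie %/% 3
  n_vh <- n_tie %/% 3
  n_mo <- n_tie - n_mg - n_vh
  # a multi-ortholog tie needs two genes in one group; fold into
  # virus-host ties when the gene table cannot support it
  if (!any(table(genes$group) >= 2) && n_mo > 0) {
    n_vh <- n_vh + n_mo
    n_mo <- 0
  }

  withr_seed(seed, {
    rows <- purrr::map(seq_len(n_s), function(i) {
      s <- design$sample[i]
      t_h <- design$time_h[i]
      rid <- function(tag, k) sprintf("%s_%s_%03d", s, tag, seq_len(k))
      n_host <- round(n_keep * host_fraction)
      n_vir <- n_keep - n_host
      keep_v <- tibble::tibble(
        read_id = rid("keep", n_vir), sample = s, time_h = t_h,
        gene_id = sample(gene_ids, n_vir, replace = TRUE),
        bit_score = round(stats::runif(n_vir, cutoff, cutoff + 150), 1),
        disposition = "kept"
      )
      keep_h <- tibble::tibble(
        read_id = rid("host", n_host), sample = s, time_h = t_h,
        gene_id = sample(host_genes, n_host, replace = TRUE),
        bit_score = round(stats::runif(n_host, cutoff, cutoff + 150), 1),
        disposition = "kept"
      )
      low <- tibble::tibble(
        read_id = rid("low", n_low), sample = s, time_h = t_h,
        gene_id = sample(gene_ids, max(n_low, 0), replace = TRUE),
        bit_score = round(stats::runif(n_low, cutoff / 2, cutoff - 0.1), 1),
        disposition = "low_score"
      )
      # each tie read gets two rows with identical top scores
      two_groups <- unique(genes$group)
      mg <- tie_rows(rid("mg", n_mg), s, t_h, cutoff, function() {
        if (length(two_groups) >= 2) {
          g2 <- sample(two_groups, 2)
          c(sample(gene_ids[genes$group == g2[1]], 1),
            sample(gene_ids[genes$group == g2[2]], 1))
        } else {
          # single-group spec: fabricate a second group's gene
          c(sample(gene_ids, 1), "othergroup_gene1")
        }
      }, "multi_group_tie")
      vh <- tie_rows(rid("vh", n_vh), s, t_h, cutoff, function() {
        c(sample(gene_ids, 1), sample(host_genes, 1))
      }, "virus_host_tie")
      # multi-ortholog tie: two genes of the same group, different orthologs
      rich_groups <- names(which(table(genes$group) >= 2))
      mo <- tie_rows(rid("mo", n_mo), s, t_h, cutoff, function() {
        g <- if (length(rich_groups) == 1) rich_groups else sample(rich_groups, 1)
        sample(gene_ids[genes$group == g], 2)
      }, "multi_ortholog")
      dplyr::bind_rows(keep_v, keep_h, low, mg, vh, mo)
    })
    hits <- dplyr::bind_rows(rows)
  })
  hits$group <- dplyr::case_when(
    hits$gene_id %in% names(groups) ~ unname(groups[hits$gene_id]),
    startsWith(hits$gene_id, "host") ~ "host_bacteria",
    TRUE ~ "other_virus_group"
  )
  hits$is_virus <- !startsWith(hits$gene_id, "host")
  truth <- dplyr::distinct(hits[, c("read_id", "disposition")])
  # a multi-ortholog tie that drew the same gene twice is really a clean
  # assignment; single-gene groups cannot produce one
  hits <- hits[, c("read_id", "sample", "time_h", "gene_id", "group",
                   "is_virus", "bit_score")]
  list_out <- list(hits = tibble::as_tibble(hits), ortholog_map = map,
                   truth = truth)
  class(list_out) <- "diel_hits_sim"
  list_out
}

tie_rows <- function(ids, s, t_h, cutoff, pick_pair, label) {
  if (length(ids) == 0) {
    return(tibble::tibble(read_id = character(), sample = character(),
                          time_h = numeric(), gene_id = character(),
                          bit_score = numeric(), disposition = character()))
  }
  purrr::map_dfr(ids, function(id) {
    pair <- pick_pair()
    sc <- round(stats::runif(1, cutoff, cutoff + 150), 1)
    tibble::tibble(read_id = id, sample = s, time_h = t_h, gene_id = pair,
                   bit_score = sc, disposition = label)
  })
}

# Deterministic two-genes-per-ortholog map over the spec'd genes, plus a
# shadow paralog gene per ortholog so multi-ortholog ties are constructible.
ortholog_map_for <- function(genes) {
  tibble::tibble(
    gene_id = genes$gene_id,
    ortholog_id = sprintf("OG%04d", seq_len(nrow(genes)))
  )
}

#' Expand simulated counts into a kept-only hit table
#'
#' Turns a [simulate_counts()] result into a read-level hit table in which
#' every viral transcript appears as one unambiguous hit and host filler
#' reads make each sample's surviving total equal the simulated library
#' total. Useful for exercising the full pipeline from the read level.
#'
#' @param sim A `diel_sim` object from [simulate_counts()].
#' @param bit_score Bit score given to every emitted hit.
#' @return A tibble of alignment hits (`read_id`, `sample`, `time_h`,
#'   `gene_id`, `group`, `is_virus`, `bit_score`).
#' @export
sim_to_hits <- function(sim, bit_score = 100) {
  cnt <- dplyr::left_join(sim$counts, sim$totals, by = "sample")
  cnt <- dplyr::left_join(cnt,
                          sim$truth[, c("gene_id", "group")], by = "gene_id")
  viral <- cnt[rep(seq_len(nrow(cnt)), cnt$count), ]
  viral$is_virus <- TRUE
  host_n <- dplyr::summarise(dplyr::group_by(cnt, sample, time_h, total),
                             viral = sum(count), .groups = "drop")
  host_n$n_host <- pmax(host_n$total - host_n$viral, 0)
  host <- host_n[rep(seq_len(nrow(host_n)), host_n$n_host), ]
  host$gene_id <- "host001"
  host$group <- "host_bacteria"
  host$is_virus <- FALSE
  all <- dplyr::bind_rows(
    viral[, c("sample", "time_h", "gene_id", "group", "is_virus")],
    host[, c("sample", "time_h", "gene_id", "group", "is_virus")]
  )
  all <- dplyr::arrange(all, sample, gene_id)
  all$read_id <- sprintf("r%07d", seq_len(nrow(all)))
  all$bit_score <- bit_score
  tibble::as_tibble(all[, c("read_id", "sample", "time_h", "gene_id", "group",
                            "is_virus", "bit_score")])
}

#' Write a simulated bundle to plain-text files
#'
#' Writes the counts, totals, truth and design of a [simulate_counts()]
#' result as tab-separated files (and the truth additionally as JSON when
#' the jsonlite package is available), so a run can be archived or fed to
#' the file-based readers.
#'
#' @param sim A `diel_sim` object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_wide <- tidyr::pivot_wider(sim$counts, names_from = "sample",
                                    values_from = "count")
  readr::write_tsv(counts_wide, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$totals, file.path(dir, "totals.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(tibble::as_tibble(sim$design), file.path(dir, "design.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         digits = NA)
  }
  invisible(dir)
}

#' Read a simulated bundle back from disk
#'
#' @param dir Directory written by [write_sim_bundle()].
#' @return A list with `counts` (long tibble), `totals`, `truth`.
#' @export
read_sim_bundle <- function(dir) {
  counts_wide <- readr::read_tsv(file.path(dir, "counts.tsv"),
                                 show_col_types = FALSE)
  counts <- tidyr::pivot_longer(counts_wide, -"gene_id",
                                names_to = "sample", values_to = "count")
  list(
    counts = counts,
    totals = readr::read_tsv(file.path(dir, "totals.tsv"),
                             show_col_types = FALSE),
    truth = readr::read_tsv(file.path(dir, "truth.tsv"),
                            show_col_types = FALSE)
  )
}
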