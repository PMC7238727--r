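mk_hit <- function(read, gene, score, group = "cyanomyovirus",
                   virus = TRUE, sample = "S001", time = 0) {
  tibble::tibble(read_id = read, sample = sample, time_h = time,
                 gene_id = gene, group = group, is_virus = virus,
                 bit_score = score)
}

test_that("score filter is inclusive at the cutoff", {
  h <- dplyr::bind_rows(mk_hit("r1", "g1", 49), mk_hit("r2", "g1", 50),
                        mk_hit("r3", "g1", 72.5))
  kept <- filter_by_score(h, 50)
  expect_setequal(kept$read_id, c("r2", "r3"))
  expect_identical(filter_by_score(h, 0), h)
  expect_equal(nrow(filter_by_score(h[0, ], 50)), 0)
})

test_that("best-hit resolution keeps unique winners and discards ties", {
  h <- dplyr::bind_rows(
    mk_hit("r1", "g1", 60), mk_hit("r1", "g2", 55),     # clean winner
    mk_hit("r2", "g1", 70),
    mk_hit("r2", "h1", 70, group = "host_bacteria", virus = FALSE),
    mk_hit("r3", "g1", 80),
    mk_hit("r3", "p1", 80, group = "cyanopodovirus")
  )
  res <- assign_best_hits(h)
  expect_equal(res$assigned$read_id, "r1")
  expect_equal(unlist(res$assigned$gene_ids), "g1")
  expect_setequal(res$discarded$reason, c("virus_host_tie", "multi_group_tie"))
  expect_equal(res$discarded$reason[res$discarded$read_id == "r2"],
               "virus_host_tie")
  expect_error(assign_best_hits(h[0, ]), "no hits")
})

test_that("a virus-host tie is discarded even when groups also differ", {
  h <- dplyr::bind_rows(
    mk_hit("r1", "g1", 70),
    mk_hit("r1", "h1", 70, group = "host_bacteria", virus = FALSE),
    mk_hit("r1", "p1", 70, group = "cyanopodovirus")
  )
  res <- assign_best_hits(h)
  expect_equal(res$discarded$reason, "virus_host_tie")
})

test_that("ortholog binning counts once within an ortholog, discards across", {
  map <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        ortholog_id = c("O1", "O1", "O2"))
  asg <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sample = "S001", time_h = 0, group = "cyanomyovirus", is_virus = TRUE,
    gene_ids = list(c("g1", "g2"),   # both in O1 -> counted once for O1
                    c("g1", "g3"),   # O1 and O2 -> discarded
                    "u1")            # unmapped -> counted under own id
  )
  res <- bin_orthologs(asg, map)
  expect_equal(res$assigned$unit_id[res$assigned$read_id == "r1"], "O1")
  expect_equal(res$assigned$unit_id[res$assigned$read_id == "r3"], "u1")
  expect_equal(res$discarded$read_id, "r2")
  expect_equal(res$discarded$reason, "multi_ortholog")
  dup_map <- tibble::tibble(gene_id = c("g1", "g1"),
                            ortholog_id = c("O1", "O2"))
  expect_error(bin_orthologs(asg, dup_map), "more than one ortholog")
})

test_that("tabulation yields explicit zeros and per-sample totals", {
  design <- diel_design(3, 4)
  asg <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    sample = c("S001", "S001", "S001", "S001", "S001", "S002"),
    time_h = c(0, 0, 0, 0, 0, 4),
    group = c(rep("cyanomyovirus", 5), "host_bacteria"),
    is_virus = c(rep(TRUE, 5), FALSE),
    unit_id = c(rep("O1", 5), "h1")
  )
  tabs <- tabulate_assignments(asg, design)
  o1 <- dplyr::filter(tabs$counts, unit_id == "O1")
  expect_equal(o1$count[o1$sample == "S001"], 5L)
  expect_equal(o1$count[o1$sample == "S003"], 0L)
  expect_equal(tabs$totals$total, c(5L, 1L, 0L))
  # relative abundance of 5 reads in a 1000-read sample
  expect_equal(relative_abundance(5, 1000), 0.005)
  asg$sample[1] <- "S999"
  expect_error(tabulate_assignments(asg, design), "not in design")
})

test_that("every read lands exactly once in counts or the discard log", {
  hs <- simulate_hits(diel_design(6, 4), gene_table(4, 2), seed = 21,
                      tie_fraction = 0.25, subcutoff_fraction = 0.15,
                      reads_per_sample = 80)
  asg <- assign_reads(hs$hits, hs$ortholog_map)
  n_reads <- dplyr::n_distinct(hs$hits$read_id)
  expect_equal(asg$n_input, n_reads)
  expect_equal(sum(asg$totals$total) + nrow(asg$discards), n_reads)
  expect_equal(anyDuplicated(asg$discards$read_id), 0L)
  # per-sample conservation
  per_sample <- dplyr::count(dplyr::distinct(hs$hits[, c("read_id", "sample")]),
                             sample)
  disc <- dplyr::count(asg$discards, sample)
  tot <- dplyr::left_join(asg$totals, disc, by = "sample")
  tot$n[is.na(tot$n)] <- 0L
  expect_equal(tot$total + tot$n,
               per_sample$n[match(tot$sample, per_sample$sample)])
})

test_that("row order of the hit table does not change the result", {
  hs <- simulate_hits(diel_design(4, 4), gene_table(3, 1), seed = 8,
                      tie_fraction = 0.2, subcutoff_fraction = 0.1,
                      reads_per_sample = 50)
  a1 <- assign_reads(hs$hits, hs$ortholog_map)
  set.seed(1)
  shuf <- hs$hits[sample(nrow(hs$hits)), ]
  a2 <- assign_reads(shuf, hs$ortholog_map)
  expect_equal(a1$counts, a2$counts)
  expect_equal(a1$totals, a2$totals)
  expect_setequal(a1$discards$read_id, a2$discards$read_id)
})

test_that("raising the score cutoff never increases any count", {
  hs <- simulate_hits(diel_design(4, 4), gene_table(3, 1), seed = 13,
                      tie_fraction = 0.2, subcutoff_fraction = 0.2,
                      reads_per_sample = 60)
  a50 <- assign_reads(hs$hits, hs$ortholog_map, cutoff = 50)
  a90 <- assign_reads(hs$hits, hs$ortholog_map, cutoff = 90)
  j <- dplyr::inner_join(a50$counts, a90$counts,
                         by = c("unit_id", "sample"), suffix = c("_50", "_90"))
  expect_true(all(j$count_90 <= j$count_50))
  expect_true(all(a90$totals$total <= a50$totals$total))
})
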