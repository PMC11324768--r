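test_that("sequence generation is deterministic and block-labelled", {
  g1 <- generate_sequences(block_sizes = c(5L, 5L), length_range = c(200L, 400L),
                           motifs_per_block = 4L, seed = 3L)
  g2 <- generate_sequences(block_sizes = c(5L, 5L), length_range = c(200L, 400L),
                           motifs_per_block = 4L, seed = 3L)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$motifs, g2$motifs)
  expect_equal(nrow(g1$truth), 10L)
  expect_equal(as.vector(table(g1$truth$block)), c(5L, 5L))

  # byte-identical FASTA from the same config + seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g1$sequences, f1)
  write_fasta(g2$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(generate_sequences(length_range = c(4L, 100L), k = 6L),
               "at least k")
})

test_that("planted motifs reach the configured enrichment within 20%", {
  gen <- generate_sequences(block_sizes = c(40L, 40L),
                            length_range = c(1500L, 2500L),
                            motifs_per_block = 10L, enrichment = 8,
                            seed = 17L)
  expect_gte(sum(Biostrings::width(gen$sequences)), 1e5)  # >= 100 kb
  for (b in names(gen$motifs)) {
    ids <- gen$truth$transcript_id[gen$truth$block == as.integer(b)]
    seqs <- gen$sequences[ids]
    expected_bg <- sum(Biostrings::width(seqs) - 5L) / 4^6
    ratios <- vapply(gen$motifs[[b]], function(m) {
      sum(Biostrings::vcountPattern(m, seqs)) / expected_bg
    }, numeric(1))
    expect_equal(mean(ratios), 8, tolerance = 0.2)
  }
})

test_that("DE table generation is deterministic and respects the null model", {
  genes <- sprintf("G%03d", 1:100)
  t1 <- generate_dge_tables(genes, 2L, shared_effect_ids = genes[1:10],
                            seed = 4L)
  t2 <- generate_dge_tables(genes, 2L, shared_effect_ids = genes[1:10],
                            seed = 4L)
  expect_identical(t1, t2)
  for (tab in t1) {
    planted <- tab$gene_id %in% genes[1:10]
    expect_true(all(abs(tab$log2fc[planted]) >= 1))
    expect_true(all(tab$pvalue[planted] < 0.001))
    expect_true(all(abs(tab$log2fc[!planted]) < 0.3))
  }
  # degenerate all-null universe -> empty consensus
  null_only <- generate_dge_tables(genes, 2L, character(0), seed = 6L)
  null_only <- lapply(null_only, function(t) { t$log2fc <- 0; t })
  expect_length(consensus_dysregulated_set(null_only, "lncRNA")$ids, 0L)
})

test_that("interaction generation plants exact triads and no more at zero background", {
  members <- list(`0` = sprintf("A%02d", 1:20))
  none <- generate_interaction_tables(members, triad_rate = 0,
                                      background_rates = c(rbp_lnc = 0,
                                                           mi_lnc = 0,
                                                           mi_rbp = 0),
                                      seed = 2L)
  expect_equal(nrow(find_triads(none$rbp_lnc, none$mi_lnc, none$mi_rbp)), 0L)

  inter <- generate_interaction_tables(members, triad_rate = 0.65,
                                       background_rates = c(rbp_lnc = 0,
                                                            mi_lnc = 0,
                                                            mi_rbp = 0),
                                       seed = 2L)
  expect_equal(nrow(inter$planted_triads), 13L)
  expect_equal(nrow(inter$incidental_triads), 0L)
  found <- find_triads(inter$rbp_lnc, inter$mi_lnc, inter$mi_rbp)
  part <- triad_participation(found, members)
  expect_equal(part$participation_pct, 65)

  i2 <- generate_interaction_tables(members, triad_rate = 0.65,
                                    background_rates = c(rbp_lnc = 0,
                                                         mi_lnc = 0,
                                                         mi_rbp = 0),
                                    seed = 2L)
  expect_identical(inter$rbp_lnc, i2$rbp_lnc)
})

test_that("incidental background triads are enumerated exactly", {
  members <- list(`0` = sprintf("A%02d", 1:15))
  inter <- generate_interaction_tables(members, n_rbps = 8L, n_mirnas = 8L,
                                       triad_rate = 0.4,
                                       background_rates = c(rbp_lnc = 0.15,
                                                            mi_lnc = 0.15,
                                                            mi_rbp = 0.25),
                                       seed = 9L)
  found <- find_triads(inter$rbp_lnc, inter$mi_lnc, inter$mi_rbp)
  key <- function(t) sort(paste(t$lncRNA_id, t$miRNA_id, t$rbp_id))
  expect_equal(key(found),
               key(rbind(inter$planted_triads, inter$incidental_triads)))
})

test_that("generated tables round-trip through the package readers", {
  members <- list(`0` = sprintf("A%02d", 1:10))
  inter <- generate_interaction_tables(members, triad_rate = 0.5, seed = 5L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(inter$mi_lnc, p)
  back <- read_edge_table(p, "mi_lnc")
  expect_equal(back$source, inter$mi_lnc$source)
  expect_equal(back$target, inter$mi_lnc$target)

  loc <- generate_localization_predictions(sprintf("A%02d", 1:10), seed = 8L)
  expect_equal(anyDuplicated(loc$predictions[, c("transcript_id", "tool")]), 0L)
  concordant <- loc$truth$transcript_id[loc$truth$concordant]
  suppressMessages(
    cons <- consensus_localization(
      loc$predictions, unique(loc$predictions$tool)))
  expect_setequal(unlist(cons$assignments), concordant)
})

test_that("synthetic Ct tables express the requested effects", {
  ct <- generate_ct_table(c(GENE1 = -2, GENE2 = 0), n_replicates = 4L,
                          noise_sd = 0.05, seed = 3L)
  res <- ddct_fold_change(ct)
  expect_equal(res$fold_change[res$gene == "GENE1"], 4, tolerance = 0.15)
  expect_equal(res$fold_change[res$gene == "GENE2"], 1, tolerance = 0.15)
})
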