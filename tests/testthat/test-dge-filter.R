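test_that("regulation calls use strict thresholds", {
  expect_equal(classify_regulation(0.15, 0.01), "up")
  expect_equal(classify_regulation(0.1, 0.001), "not_significant")  # boundary
  expect_equal(classify_regulation(-0.2, 0.06), "not_significant")
  expect_equal(classify_regulation(-0.2, 0.04), "down")
  expect_equal(classify_regulation(-0.1, 1e-9), "not_significant")  # boundary
  expect_error(classify_regulation(NaN, 0.01), "non-finite")
  expect_error(classify_regulation(0.5, NA_real_), "non-finite")
  expect_error(filter_criteria(fc_up = -1), "fc_down < 0 < fc_up")
})

test_that("consensus set is the intersection of per-dataset significance", {
  t1 <- data.frame(gene_id = c("g1", "g2", "g3"), biotype = "lncRNA",
                   log2fc = c(1, 2, 0.01), pvalue = c(1e-4, 1e-4, 0.5),
                   dataset_id = "A", stringsAsFactors = FALSE)
  t2 <- data.frame(gene_id = c("g1", "g3"), biotype = "lncRNA",
                   log2fc = c(-1, 0.02), pvalue = c(1e-3, 0.9),
                   dataset_id = "B", stringsAsFactors = FALSE)
  cs <- consensus_dysregulated_set(list(t1, t2), "lncRNA")
  # g2 significant in A only (and absent from B): excluded; g1 kept despite
  # discordant direction
  expect_equal(cs$ids, "g1")
  expect_setequal(cs$evidence$status, c("up", "down"))
  expect_error(consensus_dysregulated_set(list(), "lncRNA"), "non-empty")
})

test_that("planted shared effects are recovered exactly", {
  set.seed(101)
  genes <- sprintf("G%03d", 1:400)
  planted <- sample(genes, 30)
  tabs <- generate_dge_tables(genes, n_datasets = 2L,
                              shared_effect_ids = planted, seed = 5L)
  cs <- consensus_dysregulated_set(tabs, "lncRNA")
  expect_setequal(cs$ids, planted)
})

test_that("consensus matches a brute-force per-gene conjunction on random tables", {
  set.seed(19)
  genes <- sprintf("G%03d", 1:150)
  crit <- filter_criteria()
  tabs <- lapply(1:3, function(d) {
    data.frame(gene_id = genes, biotype = "lncRNA",
               log2fc = rnorm(length(genes), 0, 0.3),
               pvalue = runif(length(genes)),
               dataset_id = paste0("D", d), stringsAsFactors = FALSE)
  })
  brute <- Filter(function(g) {
    all(vapply(tabs, function(t) {
      row <- t[t$gene_id == g, ]
      (row$pvalue < crit$alpha) &&
        (row$log2fc > crit$fc_up || row$log2fc < crit$fc_down)
    }, logical(1)))
  }, genes)
  expect_setequal(consensus_dysregulated_set(tabs, "lncRNA", crit)$ids, brute)
})

test_that("consensus is monotone under extra tables and tighter criteria", {
  genes <- sprintf("G%03d", 1:200)
  planted <- genes[1:40]
  tabs <- generate_dge_tables(genes, n_datasets = 3L,
                              shared_effect_ids = planted,
                              effect_size = 0.5, seed = 9L)
  ids12 <- consensus_dysregulated_set(tabs[1:2], "lncRNA")$ids
  ids123 <- consensus_dysregulated_set(tabs, "lncRNA")$ids
  expect_true(all(ids123 %in% ids12))

  loose <- consensus_dysregulated_set(tabs, "lncRNA", filter_criteria())$ids
  tight <- consensus_dysregulated_set(
    tabs, "lncRNA", filter_criteria(fc_up = 0.6, fc_down = -0.6,
                                    alpha = 0.001))$ids
  expect_true(all(tight %in% loose))
})

test_that("canonical transcript mapping renames and drops unmapped genes", {
  t1 <- data.frame(gene_id = c("g1", "g2"), biotype = "lncRNA",
                   log2fc = c(1, 1), pvalue = c(1e-4, 1e-4),
                   dataset_id = "A", stringsAsFactors = FALSE)
  t2 <- t1; t2$dataset_id <- "B"
  map <- data.frame(gene_id = "g1", transcript_id = "ENST0001",
                    stringsAsFactors = FALSE)
  expect_message(
    cs <- consensus_dysregulated_set(list(t1, t2), "lncRNA",
                                     canonical_map = map),
    "without a canonical transcript")
  expect_equal(cs$ids, "ENST0001")
})

test_that("sex-biased subset subtracts control-cohort hits from disease hits", {
  base <- sprintf("L%03d", 1:180)
  sig_tab <- function(ids, all_ids, ds) {
    data.frame(gene_id = all_ids, biotype = "lncRNA",
               log2fc = ifelse(all_ids %in% ids, 2, 0),
               pvalue = ifelse(all_ids %in% ids, 1e-5, 0.9),
               dataset_id = ds, stringsAsFactors = FALSE)
  }
  ad_hits <- base[1:38]
  ctrl_hits <- c(base[38], base[170:180])  # 12 hits, overlap of exactly 1
  ad <- sig_tab(ad_hits, base, "ad_mvf")
  ctrl <- sig_tab(ctrl_hits, base, "ctrl_mvf")
  out <- sex_biased_subset(ad, ctrl, base)
  expect_length(out, 37L)
  expect_false(base[38] %in% out)

  expect_length(sex_biased_subset(ad[0, ], ctrl, base), 0L)
  expect_length(sex_biased_subset(ad, ad, base), 0L)
})
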