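test_that("AD mode with an empty dysregulated set yields an edgeless network", {
  edges <- data.frame(source = c("L1", "L2"), target = c("P1", "P2"),
                      edge_class = "rbp_lnc", evidence = NA,
                      stringsAsFactors = FALSE)
  expect_warning(net <- build_network(edges, c("L1", "L2"), mode = "AD",
                                      dysregulated_interactors = character(0)),
                 "empty dysregulated")
  expect_equal(nrow(net$edges), 0L)
  # isolated community members remain as nodes
  expect_setequal(net$nodes$node[net$nodes$role == "lncRNA"], c("L1", "L2"))
})

test_that("network construction equals a brute-force row filter", {
  set.seed(44)
  lncs <- sprintf("L%02d", 1:40)
  rbps <- sprintf("P%02d", 1:15)
  edges <- random_edge_df(lncs, rbps, 300, "rbp_lnc")
  members <- sample(lncs, 18)
  dys <- sample(rbps, 6)

  for (mode in c("AD", "comprehensive")) {
    net <- build_network(edges, members, mode = mode,
                         dysregulated_interactors = dys)
    keep <- edges$source %in% members
    if (mode == "AD") keep <- keep & edges$target %in% dys
    brute <- unique(paste(edges$source[keep], edges$target[keep]))
    expect_setequal(paste(net$edges$lncRNA_id, net$edges$interactor_id), brute)
  }

  # AD edges are a subset of comprehensive edges
  ad <- build_network(edges, members, "AD", dysregulated_interactors = dys)
  comp <- build_network(edges, members, "comprehensive")
  expect_true(all(paste(ad$edges$lncRNA_id, ad$edges$interactor_id) %in%
                    paste(comp$edges$lncRNA_id, comp$edges$interactor_id)))
})

test_that("mi_lnc networks place the lncRNA on the target side", {
  edges <- data.frame(source = c("mir-1", "mir-2"), target = c("L1", "L1"),
                      edge_class = "mi_lnc", evidence = NA,
                      stringsAsFactors = FALSE)
  net <- build_network(edges, "L1", mode = "comprehensive")
  expect_setequal(net$edges$interactor_id, c("mir-1", "mir-2"))
  expect_equal(net$nodes$role[net$nodes$node == "mir-1"], "miRNA")
})

test_that("degree ranking counts distinct partners and groups ties", {
  # star: hub RBP h with 5 lncRNA leaves
  leaves <- sprintf("L%d", 1:5)
  star <- data.frame(source = leaves, target = "h", edge_class = "rbp_lnc",
                     evidence = NA, stringsAsFactors = FALSE)
  net <- build_network(star, leaves, "comprehensive")
  rk <- degree_ranking(net, "interactor")
  expect_equal(rk$node_id, "h")
  expect_equal(rk$degree, 5L)
  rk_l <- degree_ranking(net, "lncRNA")
  expect_equal(rk_l$degree, rep(1L, 5))
  expect_equal(rk_l$rank, rep(1L, 5))  # ties share a rank
  expect_equal(rk_l$node_id, sort(leaves))  # alphabetical within ties

  set.seed(8)
  lncs <- sprintf("L%02d", 1:20)
  rbps <- sprintf("P%02d", 1:8)
  edges <- unique(random_edge_df(lncs, rbps, 120, "rbp_lnc"))
  net <- build_network(edges, lncs, "comprehensive")
  rk <- degree_ranking(net, "interactor")
  for (i in seq_len(nrow(rk))) {
    expect_equal(rk$degree[i],
                 length(unique(edges$source[edges$target == rk$node_id[i]])))
  }
  expect_true(all(diff(rk$degree) <= 0))
  # dense ranks increment only between distinct degree values
  expect_equal(rk$rank, match(rk$degree, sort(unique(rk$degree),
                                              decreasing = TRUE)))

  # both sides sum to the edge count; ranking invariant to edge order
  rk_l <- degree_ranking(net, "lncRNA")
  expect_equal(sum(rk$degree), nrow(net$edges))
  expect_equal(sum(rk_l$degree), nrow(net$edges))
  net2 <- build_network(edges[sample(nrow(edges)), ], lncs, "comprehensive")
  expect_equal(degree_ranking(net2, "interactor"), rk)
})

test_that("duplicate evidence rows collapse to one edge", {
  edges <- data.frame(source = c("L1", "L1", "L1"),
                      target = c("P1", "P1", "P2"),
                      edge_class = "rbp_lnc",
                      evidence = c("eCLIP", "PAR-CLIP", "eCLIP"),
                      stringsAsFactors = FALSE)
  net <- build_network(edges, "L1", "comprehensive")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(degree_ranking(net, "lncRNA")$degree, 2L)
})

test_that("miRNA identifier normalization unifies database spellings", {
  expect_equal(normalize_mirna_ids(c("hsa-miR-16-5p", "miR-16-5p",
                                     "MIR-16-5P", "hsa-let-7a")),
               c("mir-16-5p", "mir-16-5p", "mir-16-5p", "let-7a"))
})
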