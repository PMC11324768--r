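test_that("k-mer counts match a naive sliding-window oracle", {
  expect_equal(unname(count_kmers(c(s = "ACGT"), k = 1)[1, ]),
               c(1L, 1L, 1L, 1L))
  set.seed(23)
  seqs <- c(vapply(1:6, function(i) random_dna(sample(80:200, 1)),
                   character(1)),
            # sprinkle in ambiguous bases: windows containing them are skipped
            vapply(1:2, function(i)
              random_dna(150, alphabet = c("A", "C", "G", "T", "N")),
              character(1)))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  for (k in c(1L, 2L, 3L)) {
    counts <- count_kmers(seqs, k)
    oracle <- t(vapply(seqs, naive_kmer_counts, integer(4^k), k = k))
    expect_equal(unname(counts), unname(oracle))
    expect_equal(colnames(counts), all_kmers(k))
  }
  # pure-ACGT rows sum to L - k + 1
  pure <- seqs[1:6]
  counts6 <- count_kmers(pure, 6L)
  expect_equal(unname(rowSums(counts6)), nchar(pure) - 5L,
               ignore_attr = TRUE)
})

test_that("k=6 counts on kb-scale sequences match the oracle", {
  set.seed(31)
  seqs <- setNames(vapply(1:20, function(i) random_dna(1000), character(1)),
                   sprintf("s%02d", 1:20))
  counts <- count_kmers(seqs, 6L)
  # oracle on a subset (full 20 x 4096 naive loop is slow)
  for (i in c(1L, 9L, 20L)) {
    expect_equal(unname(counts[i, ]), unname(naive_kmer_counts(seqs[[i]], 6L)))
  }
  expect_equal(unname(rowSums(counts)), rep(995L, 20L))
})

test_that("profiles are standardized, case/U-invariant and degenerate-safe", {
  set.seed(3)
  seqs <- setNames(vapply(1:8, function(i) random_dna(500), character(1)),
                   sprintf("s%d", 1:8))
  pr <- seekr_profile(seqs, k = 4)
  nonzero <- apply(pr, 2, sd) > 0
  expect_equal(unname(colMeans(pr)), rep(0, ncol(pr)), tolerance = 1e-12)
  expect_equal(unname(apply(pr[, nonzero], 2, sd)),
               rep(1, sum(nonzero)), tolerance = 1e-12)

  lower <- setNames(tolower(chartr("T", "u", seqs)), names(seqs))
  expect_equal(seekr_profile(lower, k = 4), seekr_profile(seqs, k = 4))

  single <- seekr_profile(seqs[1], k = 4)
  expect_true(all(single == 0))

  expect_error(seekr_profile(seqs, k = 0), "positive integer")
  expect_error(seekr_profile(character(0) |> setNames(character(0)), k = 2),
               "empty")
})

test_that("Pearson adjacency matches the direct covariance formula", {
  pr <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8, -1, -2, -3, -4), nrow = 3,
               byrow = TRUE, dimnames = list(c("a", "b", "c"), NULL))
  adj <- pearson_adjacency(pr)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], -1)

  set.seed(57)
  pr <- matrix(rnorm(50), nrow = 5,
               dimnames = list(sprintf("t%d", 1:5), NULL))
  adj <- pearson_adjacency(pr)
  expect_equal(diag(adj), setNames(rep(1, 5), rownames(pr)))
  expect_equal(adj, t(adj))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(adj[i, j], naive_pearson(pr[i, ], pr[j, ]))
  }

  pr[2, ] <- 7  # constant profile
  expect_warning(adj <- pearson_adjacency(pr), "zero-variance")
  expect_true(all(adj[2, -2] == 0))
  expect_equal(adj[2, 2], 1)
})

test_that("adjusted Rand index agrees with pair counting and mclust", {
  set.seed(77)
  for (rep in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), pair_counting_ari(a, b))
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})

test_that("two disconnected triangles form two communities", {
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  adj[1:3, 1:3] <- 0.9
  adj[4:6, 4:6] <- 0.9
  diag(adj) <- 1
  as <- louvain_communities(adj, seed = 0)
  expect_equal(length(as$sizes), 2L)
  expect_equal(adjusted_rand_index(as$labels, rep(1:2, each = 3)), 1)
  expect_true(is.na(as$null_label))
})

test_that("Louvain recovers a planted 4-block partition (ARI >= 0.9)", {
  set.seed(2024)
  pp <- planted_partition_adjacency()
  as <- louvain_communities(pp$adj, seed = 0, restarts = 10)
  ari <- adjusted_rand_index(as$labels[names(pp$labels)], pp$labels)
  expect_gte(ari, 0.9)
  # labels are size-ordered among placed communities
  placed <- setdiff(names(as$sizes), as.character(as$null_label))
  expect_true(all(diff(as$sizes[placed]) <= 0))
})

test_that("community detection is deterministic and beats singletons on modularity", {
  set.seed(99)
  pp <- planted_partition_adjacency(n_blocks = 3L, block_size = 15L)
  a1 <- louvain_communities(pp$adj, seed = 4, restarts = 5)
  a2 <- louvain_communities(pp$adj, seed = 4, restarts = 5)
  expect_identical(a1$labels, a2$labels)

  g <- a1$graph
  singleton_mod <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                                      weights = igraph::E(g)$weight)
  expect_gte(a1$modularity, singleton_mod)
})

test_that("isolated transcripts are pooled into the trailing null community", {
  set.seed(12)
  pp <- planted_partition_adjacency(n_blocks = 2L, block_size = 10L)
  adj <- pp$adj
  # append two nodes uncorrelated with everything
  n <- nrow(adj)
  big <- matrix(-0.5, n + 2, n + 2)
  big[1:n, 1:n] <- adj
  diag(big) <- 1
  ids <- c(rownames(adj), "iso1", "iso2")
  dimnames(big) <- list(ids, ids)
  as <- louvain_communities(big, seed = 0)
  expect_equal(as$null_label, max(as$labels))
  expect_equal(sort(names(as$labels[as$labels == as$null_label])),
               c("iso1", "iso2"))

  all_iso <- matrix(-1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(all_iso) <- 1
  expect_warning(as0 <- louvain_communities(all_iso), "null community")
  expect_equal(unname(as0$labels), rep(0L, 3L))
})

test_that("permuting transcript order does not change the partition", {
  set.seed(5)
  pp <- planted_partition_adjacency(n_blocks = 3L, block_size = 12L)
  perm <- sample(nrow(pp$adj))
  as1 <- louvain_communities(pp$adj, seed = 1, restarts = 5)
  as2 <- louvain_communities(pp$adj[perm, perm], seed = 1, restarts = 5)
  common <- names(as1$labels)
  expect_equal(adjusted_rand_index(as1$labels[common], as2$labels[common]), 1)
})
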